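# Control file for the sexual-conflict-with-decoy population simulator.
# One "key = value" pair per line; '#' starts a comment; omitted keys take
# the published defaults shown here.

# -- simulation ------------------------------------------------------------
N            = 10000     # diploid individuals (constant)
generations  = 15000
n_encounters = 20        # males encountered per female per generation
mu           = 5e-5      # mutation rate per locus per gamete per generation
window       = 500       # generations per substitution-rate window
replicates   = 20
seed         = 1

# initial allelic values (alleles are integers 0..allele_max)
init_male    = 0
init_female  = 5
init_decoy   = 16
init_neutral = 30

# -- model -----------------------------------------------------------------
P_opt      = 0.5         # optimal female mating rate
B_max      = 10          # maximum offspring per female
s_w        = 0.3         # fecundity penalty scale
x_w        = 2           # fecundity penalty exponent
s_p        = 0.1         # baseline mating-rate decay scale
x_p        = 2           # baseline mating-rate decay exponent
si         = 0.05        # positional interference scale (male-decoy distance)
xi         = 2           # positional interference exponent
sd         = 0.04        # deviation penalty scale (|D_MF - D_opt|)
xd         = 2           # deviation penalty exponent
c0         = 0.25        # positional interference magnitude (fraction of P_opt)
D_opt      = 0.08        # optimal male-female distance for decoy function
allele_max = 50
normalize  = 1           # distances on phenotypes divided by allele_max
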