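# Shared fixtures: the shipped reference set and a few handy constructors.

ref <- reference_params()

linear_params <- function(kel = 0.25 / 2.8, v1 = 2.8, v2 = 2.8, q = 0.6) {
  tmdd_params(kel = kel, kon = 0, koff = 3.69, kint = 4.37,
              ksyn = 3.48, kdeg = 2, v1 = v1, v2 = v2, q = q)
}

adult70 <- subject("custom", 70)
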