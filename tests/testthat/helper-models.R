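# shared fixtures: all built in code, nothing downloaded

two_bead_pdb <- function() make_toy_peptide_pdb("GA")

# deterministic 5-bead toy with mixed charges
five_bead_toy <- function(seed = 1) {
  make_toy("random-charge-set", n = 5, extent = 6, sigma = 4, seed = seed)
}

# translate a protein model rigidly
shift_model <- function(model, dx = 0, dy = 0, dz = 0) {
  model$beads$x <- model$beads$x + dx
  model$beads$y <- model$beads$y + dy
  model$beads$z <- model$beads$z + dz
  model
}

# a cached copy of the synthetic reference protein
ifn_model_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- ifn_alpha2a_model()
    cache
  }
})
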