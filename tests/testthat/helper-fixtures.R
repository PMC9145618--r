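# Shared fixtures, built once per test run.

# Small default-style phantom: 12 slices of 64x64, vessels + noise.
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(
        phantom_config(n_slices = 12, slice_shape = c(64, 64), seed = 11))
    }
    cache
  }
})

small_partition <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- segment_volume(small_phantom()$volume)
    cache
  }
})

small_mvar <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- mvar_compress(small_phantom()$volume, small_partition())
    }
    cache
  }
})

rand_u16 <- function(nr, nc, seed = 1) {
  set.seed(seed)
  matrix(sample(0L:65535L, nr * nc, replace = TRUE), nr, nc)
}

full_mask <- function(nr, nc) matrix(TRUE, nr, nc)

reference_quality_table <- function() {
  utils::read.csv(system.file("extdata", "cta_reference_quality.csv",
                              package = "aroi"))
}

reference_size_table <- function() {
  utils::read.csv(system.file("extdata", "cta_reference_sizes.csv",
                              package = "aroi"), check.names = FALSE)
}
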