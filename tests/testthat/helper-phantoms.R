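# shared fixtures, built in code and cached for the duration of the run

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# digital disc mask
disc_mask <- function(n, r_px, ctr = c((n + 1) / 2, (n + 1) / 2)) {
  rr <- outer((seq_len(n) - ctr[1L])^2, (seq_len(n) - ctr[2L])^2, `+`)
  sqrt(rr) <= r_px
}

# default-population feature table (truth masks), 100 cells per class
population_features <- function() {
  cache_get("pop100", function() {
    specs <- sample_population(100L, rng_seed = 7L)
    suppressMessages(population_feature_table(specs, segment = "truth",
                                              rng_seed = 7L))
  })
}

# classic Evans-Fung discocyte rendered cleanly
classic_phantom <- function(pixel_size = 0.08) {
  cache_get(paste0("classic", pixel_size), function() {
    render_phantom(phantom_spec(), pixel_size = pixel_size, pad_um = 3)
  })
}

# erode a logical mask by one 4-neighbour step
erode1 <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  out <- mask
  out[1L, ] <- FALSE; out[m, ] <- FALSE; out[, 1L] <- FALSE; out[, n] <- FALSE
  inner <- mask[2:(m - 1L), 2:(n - 1L)] &
    mask[1:(m - 2L), 2:(n - 1L)] & mask[3:m, 2:(n - 1L)] &
    mask[2:(m - 1L), 1:(n - 2L)] & mask[2:(m - 1L), 3:n]
  out[2:(m - 1L), 2:(n - 1L)] <- inner
  out
}

rms <- function(x) sqrt(mean(x^2))
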