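## shared small fixtures, built in code

## a coarse (64^3, 0.5 mm) phantom covering the same 32 mm scene as the
## full-resolution default; cached per test run
coarse_spec <- function(noise_sd = 0, seed = 5L, ...) {
  phantom_spec(dims = 64, spacing = 0.5, noise_sd = noise_sd, seed = seed, ...)
}

.case_cache <- new.env(parent = emptyenv())
cached_case <- function(spec) {
  key <- digest_key(spec)
  if (is.null(.case_cache[[key]])) .case_cache[[key]] <- generate_case(spec)
  .case_cache[[key]]
}
digest_key <- function(x) paste(deparse(x), collapse = "")

## random small label map on an 8^3 grid
random_label8 <- function(p = 0.5) {
  g <- voxel_grid(array(0, c(8, 8, 8)))
  label_map(array(as.integer(stats::runif(512) < p), c(8, 8, 8)), g)
}

## brute-force Dice oracle by explicit voxel set enumeration
dice_oracle <- function(a, b, code = 1L) {
  A <- which(as.vector(a$codes) == code)
  B <- which(as.vector(b$codes) == code)
  if (length(A) + length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}
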