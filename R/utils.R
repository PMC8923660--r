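# Internal helpers shared across modules.

#' Wrap angles to the half-open interval (-180, 180]
#'
#' All cue-relative directions in the package live on `(-180, 180]` degrees,
#' mathematical convention (0 = +x axis, counterclockwise positive).
#'
#' @param a Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped to `(-180, 180]`.
#' @examples
#' wrap_angle(c(190, -180, 540))
#' @export
wrap_angle <- function(a) {
  a - 360 * ceiling((a - 180) / 360)
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
# `seed = NULL` means "use the current stream" so nested simulators can be
# driven by one top-level seed.
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Draw k session/stage seeds reproducibly from one master seed; kept strictly
# below .Machine$integer.max so they remain valid R integer seeds.
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Validation helper: stop with a message naming the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
  }
}

# Population SD (divide by n), the z-scoring convention used package-wide.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Cue azimuth in degrees for a screen side label.
side_angle <- function(side) {
  ifelse(side == "right", 0, 180)
}

# Standard error of the mean.
sem <- function(x) stats::sd(x) / sqrt(length(x))

# MD5 digest of an R object via its canonical JSON serialization; used to
# stamp analysis artifacts with the configuration that produced them.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}
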