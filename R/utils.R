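#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG stream seeded with `seed`, restoring any
# pre-existing global RNG state afterwards. All stochastic code in the
# package goes through this so that a single integer seed determines every
# draw and user-level RNG state is never disturbed.
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside the 32-bit signed integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# md5 of the canonical JSON serialization of an R object; used to fingerprint
# configurations inside evaluation reports and run manifests.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

#' Standard 19-channel montage
#'
#' The 10-20 electrode labels used throughout the package, in acquisition
#' order: a fronto-central montage that avoids posterior sites (chosen for
#' recordings from a supine patient).
#'
#' @return Character vector of 19 channel labels.
#' @export
montage_1020 <- function() {
  c("Oz", "O1", "O2", "Cz", "C3", "C4", "T7", "T8", "Fz",
    "FC1", "FC2", "FC5", "FC6", "F3", "F4", "F7", "F8", "AF3", "AF4")
}

#' Default frequency bands for band-power features
#'
#' @return Data frame with columns `name`, `low`, `high` (Hz): theta 4-7,
#'   alpha 8-13, low_beta 14-20, high_beta 21-30, gamma 31-45.
#' @export
standard_bands <- function() {
  data.frame(
    name = c("theta", "alpha", "low_beta", "high_beta", "gamma"),
    low  = c(4, 8, 14, 21, 31),
    high = c(7, 13, 20, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Default hemisphere assignment of the 19-channel montage
#'
#' Used by the inter-hemispheric asymmetry features. Midline electrodes are
#' excluded from both sets.
#'
#' @return List with character vectors `left`, `right`, `midline`.
#' @export
hemisphere_map <- function() {
  list(
    left    = c("O1", "C3", "T7", "FC1", "FC5", "F3", "F7", "AF3"),
    right   = c("O2", "C4", "T8", "FC2", "FC6", "F4", "F8", "AF4"),
    midline = c("Oz", "Cz", "Fz")
  )
}
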