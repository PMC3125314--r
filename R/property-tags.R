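#' Qualitative property tags for interaction terms
#'
#' Ten qualitative shape classes for the scalar functions entering a network
#' model: constants, sigmoids and their complements (Hill-type with zero slope
#' at the origin), saturating increasing/decreasing kinetics, exact-threshold
#' decreasing terms, and unbounded increasing terms. Every term in a
#' qualitative model carries one tag per scalar argument; instantiation draws
#' a concrete parametric function realizing that tag, and
#' [verify_property()] checks the realization numerically.
#'
#' @format A character vector of the ten tag ids.
#' @export
property_tags <- c(
  "nonnegative-constant",
  "positive-constant",
  "sigmoidal",
  "complementary-sigmoidal",
  "constant-sigmoidal",
  "constant-complementary-sigmoidal",
  "increasing-asymptotically-constant",
  "decreasing-asymptotically-null",
  "decreasing-exactly-null",
  "increasing-asymptotically-unbounded"
)

# Monotonicity class of each tag; used for kind/tag compatibility (saturation
# assumption: production-modifier terms non-decreasing, repression-modifier
# terms non-increasing).
tag_direction <- function(tag) {
  switch(tag,
    "nonnegative-constant" = ,
    "positive-constant" = "constant",
    "sigmoidal" = ,
    "constant-sigmoidal" = ,
    "increasing-asymptotically-constant" = ,
    "increasing-asymptotically-unbounded" = "non-decreasing",
    "complementary-sigmoidal" = ,
    "constant-complementary-sigmoidal" = ,
    "decreasing-asymptotically-null" = ,
    "decreasing-exactly-null" = "non-increasing",
    stop("unknown property tag: ", tag, call. = FALSE)
  )
}

# Tags whose realizations vanish at zero (candidates for terms that must be
# null at the lower saturation level of the regulated species).
tag_zero_at_zero <- function(tag) {
  tag %in% c("sigmoidal", "increasing-asymptotically-unbounded")
}

assert_tag <- function(tag) {
  if (length(tag) != 1 || !tag %in% property_tags) {
    stop("unknown property tag: ", paste(tag, collapse = ", "), call. = FALSE)
  }
  tag
}
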