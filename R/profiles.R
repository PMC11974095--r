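#' Haplotype-specific copy number profiles
#'
#' A profile holds two nonnegative integer vectors of per-segment copy
#' numbers, one for each parental haplotype, each entry bounded by `c_max`.
#' The normal (diploid) profile has one copy of each haplotype everywhere.
#'
#' @param hap1,hap2 integer vectors of per-segment copy numbers.
#' @param c_max maximum per-haplotype copy number (default 19).
#' @return Object of class `evocn_profile` with fields `hap1`, `hap2`.
#' @export
cn_profile <- function(hap1, hap2, c_max = 19L) {
  hap1 <- as.integer(hap1); hap2 <- as.integer(hap2)
  if (length(hap1) != length(hap2))
    stopf("profile: haplotype vectors differ in length")
  if (any(hap1 < 0L) || any(hap2 < 0L))
    stopf("profile: negative copy number")
  if (any(hap1 > c_max) || any(hap2 > c_max))
    stopf("profile: copy number exceeds c_max = %d", c_max)
  structure(list(hap1 = hap1, hap2 = hap2, c_max = as.integer(c_max)),
            class = "evocn_profile")
}

#' The normal diploid profile
#' @param L number of segments.
#' @inheritParams cn_profile
#' @export
normal_profile <- function(L, c_max = 19L) {
  cn_profile(rep(1L, L), rep(1L, L), c_max = c_max)
}

total_copy <- function(profile) profile$hap1 + profile$hap2

## Canonical string key: used for caching and clone identity.
profile_key <- function(profile) {
  paste(c(profile$hap1, profile$hap2), collapse = ",")
}

profiles_equal <- function(a, b) {
  identical(a$hap1, b$hap1) && identical(a$hap2, b$hap2)
}

#' @export
print.evocn_profile <- function(x, ...) {
  cat(sprintf("<copy number profile, L = %d, c_max = %d>\n",
              length(x$hap1), x$c_max))
  cat(" hap1:", paste(utils::head(x$hap1, 25), collapse = " "),
      if (length(x$hap1) > 25) "...\n" else "\n")
  cat(" hap2:", paste(utils::head(x$hap2, 25), collapse = " "),
      if (length(x$hap2) > 25) "...\n" else "\n")
  invisible(x)
}
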