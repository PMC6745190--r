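#' Perturb one class's value coefficients
#'
#' Scales the whole coefficient row of a class by `factor`, leaving the other
#' classes untouched (the perturbation treats a class's coefficients as a
#' block, the convention of the elasticity analysis).
#'
#' @param vc Value-coefficient matrix.
#' @param class Class name (one of [lulc_classes()]).
#' @param factor Positive multiplier; `1.5` is a +50% adjustment.
#' @return Adjusted copy of `vc`.
#' @export
adjust_vc <- function(vc, class, factor) {
  if (!class %in% rownames(vc)) stop("unknown class: ", class)
  if (!is.finite(factor) || factor <= 0 || factor > 2) {
    stop("`factor` must lie in (0, 2]")
  }
  vc[class, ] <- vc[class, ] * factor
  vc
}

#' Coefficient of sensitivity (elasticity) of the total ESV
#'
#' The standard elasticity of the total ecosystem service value with respect
#' to a proportional adjustment of one class's value coefficients:
#' `CS = ((ESV_adj - ESV) / ESV) / delta`, computed by re-valuing the
#' landscape with the class's coefficient row scaled by `1 + delta`. Under
#' the linear benefit-transfer model CS equals the class's share of the total
#' value and is independent of `delta`. `CS <= 1` means the estimate is
#' inelastic — robust to coefficient uncertainty. A class with an all-zero
#' coefficient row has CS defined as 0 (the formula's denominator would be
#' 0/0).
#'
#' @param areas_ha Named per-class areas in hectares.
#' @param vc Value-coefficient matrix.
#' @param class Class whose coefficients are adjusted.
#' @param delta Signed fractional adjustment (default `0.5`, i.e. +50%).
#' @return List with `pct_change_total` (% change of the total ESV, signed),
#'   `cs` (dimensionless, nonnegative), and `elastic` (`cs > 1`).
#' @export
coefficient_of_sensitivity <- function(areas_ha, vc = value_coefficients(),
                                       class, delta = 0.5) {
  if (delta == 0) stop("`delta` must be nonzero")
  esv_i <- total_esv(areas_ha, vc)
  if (esv_i <= 0) stop("total ESV must be positive")
  if (all(vc[class, ] == 0)) {
    return(list(pct_change_total = 0, cs = 0, elastic = FALSE))
  }
  esv_j <- total_esv(areas_ha, adjust_vc(vc, class, 1 + delta))
  rel <- (esv_j - esv_i) / esv_i
  cs <- rel / delta
  list(pct_change_total = 100 * rel, cs = cs, elastic = cs > 1)
}

#' Sensitivity table over classes and years
#'
#' Runs [coefficient_of_sensitivity()] for every class and every year of an
#' area table — the layout of the published sensitivity table (percentage
#' change of the total under a +/-50% coefficient adjustment, and CS). The
#' reported percentage is the magnitude of the change (the +50% and -50%
#' adjustments are symmetric under the linear model).
#'
#' @param area_table Long data.frame (`year`, `class`, `area_1e4_ha` or
#'   `area_ha`).
#' @param vc Value-coefficient matrix.
#' @param delta Fractional adjustment magnitude (default 0.5).
#' @return data.frame with columns `class`, `year`, `pct_change`, `cs`.
#' @export
sensitivity_table <- function(area_table, vc = value_coefficients(),
                              delta = 0.5) {
  years <- sort(unique(area_table$year))
  out <- expand.grid(class = lulc_classes(), year = years,
                     stringsAsFactors = FALSE)
  res <- Map(function(cl, y) {
    areas <- area_row(area_table, y, unit = "ha")
    if (total_esv(areas, vc) <= 0) {   # valueless year: nothing to perturb
      return(list(pct_change_total = 0, cs = 0, elastic = FALSE))
    }
    coefficient_of_sensitivity(areas, vc, cl, delta)
  }, out$class, out$year)
  out$pct_change <- abs(vapply(res, `[[`, numeric(1), "pct_change_total"))
  out$cs <- vapply(res, `[[`, numeric(1), "cs")
  out
}
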