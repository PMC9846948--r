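# Side-ratio statistics: linear volume dependence, solvent influence
# ranking, and correlations with bulk solvent properties.

#' Linear fit of side ratio versus organic-solvent volume
#'
#' Ordinary least squares of the (2 0 0)/(1 1 0)-style side ratio on the
#' added organic-solvent volume. The side ratio of the grown crystals is
#' close to linear in the volume over the working range, so the slope (per
#' microliter) summarizes how strongly a solvent elongates the habit.
#'
#' @param series data.frame with columns \code{volume} (microliter) and
#'   \code{side_ratio} (dimensionless); at least 3 observations.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{slope_se}, \code{n}.
#' @examples
#' s <- data.frame(volume = seq(50, 250, 50),
#'                 side_ratio = 0.002 * seq(50, 250, 50) + 0.1)
#' fit_sideratio(s)$slope   # 0.002
#' @export
fit_sideratio <- function(series) {
  stopifnot(all(c("volume", "side_ratio") %in% names(series)))
  if (nrow(series) < 3) stop("need at least 3 observations")
  if (stats::var(series$volume) == 0) stop("volumes have zero variance")
  if (any(series$volume < 0)) stop("volumes must be >= 0")
  fit <- stats::lm(side_ratio ~ volume, data = series)
  # exact (noiseless) inputs are legitimate here; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0        # constant response
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       slope_se = unname(sm$coefficients[2, 2]),
       n = nrow(series))
}

#' Rank solvents by their morphology influence
#'
#' Stable descending sort of solvents by side ratio at a fixed added
#' volume; a larger ratio means a stronger elongation of the habit. Exact
#' ties are broken alphabetically and flagged.
#'
#' @param ratios named numeric vector (solvent name -> side ratio).
#' @return data.frame with columns \code{solvent}, \code{side_ratio},
#'   \code{rank}; attribute \code{"ties"} lists tied solvent names (if any).
#' @export
rank_solvents <- function(ratios) {
  if (length(ratios) == 0) stop("empty ratio map")
  if (is.null(names(ratios)) || any(!nzchar(names(ratios)))) {
    stop("ratios must be named by solvent")
  }
  ord <- order(-ratios, names(ratios))
  out <- data.frame(solvent = names(ratios)[ord],
                    side_ratio = unname(ratios[ord]),
                    rank = seq_along(ratios))
  dup <- unique(out$side_ratio[duplicated(out$side_ratio)])
  ties <- out$solvent[out$side_ratio %in% dup]
  if (length(ties)) {
    message("tie(s) broken alphabetically: ", paste(ties, collapse = ", "))
    attr(out, "ties") <- ties
  }
  out
}

#' Correlate side ratios with solvent properties
#'
#' For each bulk property (relative permittivity, dipole moment, density,
#' carbon count) computes the Spearman rank correlation (primary: the claims
#' are monotone trends, not linear laws) and the Pearson coefficient, with
#' the trend sign. Optional permutation p-values are available; with only a
#' handful of solvents no significance claim is made by default.
#'
#' @param ratios named numeric vector (solvent -> side ratio).
#' @param props data.frame with a \code{name} column plus numeric property
#'   columns (default the four standard ones found in the table).
#' @param properties which property columns to use; default all numeric
#'   columns except \code{name}.
#' @param n_perm if > 0, permutation-null p-values for the Spearman
#'   coefficient with this many label permutations.
#' @param seed RNG seed for the permutations.
#' @return data.frame: \code{property}, \code{spearman}, \code{pearson},
#'   \code{sign}, and \code{p_perm} when requested.
#' @export
property_correlations <- function(ratios, props, properties = NULL,
                                  n_perm = 0, seed = 1) {
  if (length(ratios) < 3) stop("need at least 3 matched solvents")
  stopifnot("name" %in% names(props))
  unmatched <- setdiff(names(ratios), props$name)
  if (length(unmatched)) {
    stop("solvent(s) missing from the property table: ",
         paste(unmatched, collapse = ", "))
  }
  props <- props[match(names(ratios), props$name), , drop = FALSE]
  if (is.null(properties)) {
    properties <- names(props)[vapply(props, is.numeric, logical(1))]
  }
  r <- unname(ratios)
  rows <- lapply(properties, function(p) {
    x <- props[[p]]
    sp <- suppressWarnings(stats::cor(x, r, method = "spearman"))
    pe <- suppressWarnings(stats::cor(x, r, method = "pearson"))
    row <- data.frame(property = p, spearman = sp, pearson = pe,
                      sign = ifelse(sp > 0, "increasing",
                                    ifelse(sp < 0, "decreasing", "flat")))
    if (n_perm > 0) {
      set.seed(as.integer(seed))
      null <- replicate(n_perm, suppressWarnings(
        stats::cor(x, sample(r), method = "spearman")))
      row$p_perm <- mean(abs(null) >= abs(sp))
    }
    row
  })
  do.call(rbind, rows)
}

#' Bundled reference properties of the nine organic solvents
#'
#' Editable handbook-style values (25 C) for the nine polar aprotic
#' crystallization solvents: relative permittivity, dipole moment (Debye),
#' liquid density (g/cm^3) and carbon count. Shipped as data, not ground
#' truth; replace with measured values where available.
#'
#' @return data.frame with columns \code{name},
#'   \code{relative_permittivity}, \code{dipole_moment}, \code{density},
#'   \code{n_carbon}.
#' @export
solvent_reference_properties <- function() {
  path <- system.file("extdata", "solvent_properties.csv",
                      package = "crysmorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
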