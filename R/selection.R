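#' AIC in the Mx convention
#'
#' `AIC = -2LL - 2*df`, the convention used by the Mx family of twin
#' modeling programs, which reproduces the published model-fit table from
#' its -2LL/df columns. The textbook form `-2LL + 2*k` (k free
#' parameters) is available via `convention = "textbook"` but is not used
#' for comparisons against the published table.
#'
#' @param neg2ll Minus twice the log-likelihood.
#' @param df Model degrees of freedom (Mx convention) or number of free
#'   parameters (textbook convention).
#' @param convention `"mx"` (default) or `"textbook"`.
#' @return AIC value.
#' @export
aic <- function(neg2ll, df, convention = c("mx", "textbook")) {
  convention <- match.arg(convention)
  stopifnot(df >= 0)
  if (convention == "mx") neg2ll - 2 * df else neg2ll + 2 * df
}

.fit_fields <- function(x) {
  if (inherits(x, "ace_fit"))
    list(model = x$model, neg2ll = x$neg2ll, df = x$df)
  else list(model = if (!is.null(x$model)) x$model else NA_character_,
            neg2ll = x$neg2ll, df = x$df)
}

#' Likelihood-ratio test between nested model fits
#'
#' Twice the difference in log-likelihoods (`delta_chi2`), tested against
#' a chi-square with the difference in degrees of freedom. Small negative
#' statistics (numerical noise, tolerance 1e-6) are clipped to 0; larger
#' negatives signal a convergence failure.
#'
#' @param nested,parent Fits (an `ace_fit` or any list with `neg2ll`,
#'   `df`, optionally `model`); `nested` must have larger df.
#' @return Data frame with `comparison`, `delta_chi2`, `delta_df`, `p`.
#' @export
lrt <- function(nested, parent) {
  a <- .fit_fields(nested); b <- .fit_fields(parent)
  if (!(a$df > b$df)) stop("nested model must have larger df than parent")
  d <- a$neg2ll - b$neg2ll
  if (d < -1e-6)
    stop("nested fit has lower -2LL than parent (", format(d),
         "): convergence failure")
  d <- max(d, 0)
  ddf <- a$df - b$df
  data.frame(comparison = paste(a$model, "vs.", b$model),
             delta_chi2 = d, delta_df = ddf,
             p = stats::pchisq(d, ddf, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Select the best-fitting model by LRT and AIC
#'
#' Walks the published decision sequence: each sub-model is compared to
#' its declared parent by likelihood-ratio test; a sub-model whose test
#' is significant at `alpha` is rejected (a worse fit), and among the
#' general model and the non-rejected sub-models the lowest Mx-convention
#' AIC wins. Sub-models whose parent was itself rejected are compared to
#' the nearest non-rejected ancestor's published comparison partner as
#' declared in `parents`.
#'
#' @param fits Named list of fits (names or `$model` give ids), including
#'   the general model.
#' @param parents Named character vector mapping each sub-model id to the
#'   id it is LRT-compared against. Default: the ladder II vs I,
#'   III vs II, IV vs III, V vs II, VI vs II.
#' @param alpha LRT significance level, default 0.05.
#' @return The selected model id, with the comparison table as
#'   `attr(, "comparisons")`.
#' @export
select_best <- function(fits,
                        parents = c(II = "I", III = "II", IV = "III",
                                    V = "II", VI = "II"),
                        alpha = 0.05) {
  ids <- vapply(fits, function(f) .fit_fields(f)$model, character(1))
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) names(fits) <- ids
  if (!length(fits)) stop("no fits supplied")
  if (length(fits) == 1L) return(names(fits))
  rejected <- character(0)
  comp <- NULL
  for (id in names(parents)) {
    if (!(id %in% names(fits)) || !(parents[[id]] %in% names(fits))) next
    row <- lrt(fits[[id]], fits[[parents[[id]]]])
    comp <- rbind(comp, row)
    if (row$p <= alpha) rejected <- c(rejected, id)
  }
  candidates <- setdiff(names(fits), rejected)
  aics <- vapply(fits[candidates], function(f) {
    ff <- .fit_fields(f); aic(ff$neg2ll, ff$df)
  }, numeric(1))
  best <- candidates[which.min(aics)]
  structure(best, comparisons = comp)
}
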