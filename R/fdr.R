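#' FDR q-values for a vector of p-values
#'
#' Computes multiple-testing-adjusted q-values. The default is the
#' Benjamini-Hochberg step-up adjustment,
#' `q(i) = min over j >= i of m p(j) / j` on sorted p-values mapped back to
#' the input order (as in `stats::p.adjust(method = "BH")`), which assumes
#' the proportion of true nulls is 1 and therefore satisfies
#' `q >= p` everywhere. The `"storey"` option rescales the BH values by an
#' estimate of the true-null proportion `pi0 = #\{p > lambda\} /
#' (m (1 - lambda))`, clamped to `[1/m, 1]`; with the modest scan sizes this
#' package targets the plug-in `pi0` is noisy, which is why BH is the
#' default.
#'
#' `NA` entries (non-estimable SNPs) are excluded from `m` and returned as
#' `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @param method `"BH"` (default) or `"storey"`.
#' @param lambda tuning constant of the Storey null-proportion estimate.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' fdr_qvalues(c(0.005, 0.1, 0.9))   # 0.015 0.15 0.90
#' @export
fdr_qvalues <- function(p, method = c("BH", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (!any(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  q <- p.adjust(pv, method = "BH")
  if (method == "storey") {
    m <- length(pv)
    pi0 <- min(1, max(1 / m, mean(pv > lambda) / (1 - lambda)))
    q <- pmin(1, pi0 * q)
  }
  out[ok] <- q
  out
}
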