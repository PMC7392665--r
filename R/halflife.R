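# Joining frameshift candidates with protein half-life measurements and
# testing the proline-delta group effect: candidates whose skipped isoform
# gains proline ("P-rich") are expected to show shorter half-lives than the
# bulk proteome.

#' Join candidates with a half-life table and assign proline groups
#'
#' Retains candidate genes with a measured half-life and a PSI below
#' `psi_cutoff` ("Skipped"), and partitions them into `P-decreased`,
#' `P-unchanged` and `P-rich` via [proline_group()]. The returned long table
#' also carries every measured protein under group `All`.
#'
#' @param candidates data.frame with `gene_id`, `psi` (percent in the cell
#'   line of interest), `P_fl`, `P_fs` (proline content of both C-termini,
#'   percent).
#' @param halflife data.frame with `gene_id`, `half_life_h` (hours > 0).
#' @param psi_cutoff Skipping call threshold (strict `<`), default 90.
#' @return data.frame with `gene_id`, `half_life_h`, `group`; group sizes in
#'   attribute `"n"`, dropped-candidate counts in attribute `"dropped"`.
#' @export
join_halflife <- function(candidates, halflife, psi_cutoff = 90) {
  stopifnot(all(c("gene_id", "psi", "P_fl", "P_fs") %in% names(candidates)),
            all(c("gene_id", "half_life_h") %in% names(halflife)))
  if (any(halflife$half_life_h <= 0, na.rm = TRUE)) {
    stop("half-lives must be positive")
  }
  measured <- candidates$gene_id %in% halflife$gene_id
  skipped <- !is.na(candidates$psi) & candidates$psi < psi_cutoff
  keep <- candidates[measured & skipped, , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop("empty join: no skipped candidate has a measured half-life; ",
         sum(measured), "/", nrow(candidates), " candidate gene ids match ",
         "the half-life table")
  }
  keep$group <- proline_group(keep$P_fl, keep$P_fs)
  all_rows <- data.frame(gene_id = halflife$gene_id,
                         half_life_h = halflife$half_life_h,
                         group = "All", stringsAsFactors = FALSE)
  hl <- halflife$half_life_h[match(keep$gene_id, halflife$gene_id)]
  sk_rows <- data.frame(gene_id = rep(keep$gene_id, 2L),
                        half_life_h = rep(hl, 2L),
                        group = c(rep("Skipped", nrow(keep)), keep$group),
                        stringsAsFactors = FALSE)
  out <- rbind(all_rows, sk_rows)
  attr(out, "n") <- table(out$group)
  attr(out, "dropped") <- c(no_halflife = sum(!measured & skipped),
                            not_skipped = sum(measured & !skipped))
  out
}

#' Compare half-life groups against the full proteome
#'
#' Tests every group (other than `All`) against `All` with a two-sided
#' unpaired t test. By default Welch's unequal-variance variant is applied
#' to log-transformed half-lives (half-life distributions are strongly
#' right-skewed); both choices are configurable and recorded in the output.
#' A Wilcoxon rank-sum p value and a Benjamini-Hochberg column across the
#' group comparisons are also reported. Groups with fewer than `min_n`
#' members are skipped.
#'
#' @param records Long table from [join_halflife()].
#' @param log_transform Test on `log(half_life_h)` (default `TRUE`).
#' @param var_equal Classic Student variant instead of Welch
#'   (default `FALSE`).
#' @param min_n Minimum group size to test (default 3).
#' @return data.frame with `group`, `n`, `median_h`, `mean_h`, `p_t`,
#'   `p_wilcox`, `p_t_BH`, `tested`; test settings in attribute
#'   `"settings"`.
#' @export
compare_groups <- function(records, log_transform = TRUE, var_equal = FALSE,
                           min_n = 3L) {
  stopifnot(all(c("half_life_h", "group") %in% names(records)))
  if (!"All" %in% records$group) stop("records must contain an 'All' group")
  ref <- records$half_life_h[records$group == "All"]
  groups <- setdiff(unique(records$group), "All")
  tv <- if (log_transform) log else identity
  rows <- lapply(c("All", groups), function(g) {
    v <- records$half_life_h[records$group == g]
    tested <- g != "All" && length(v) >= min_n
    p_t <- p_w <- NA_real_
    if (tested) {
      p_t <- stats::t.test(tv(v), tv(ref), var.equal = var_equal)$p.value
      p_w <- stats::wilcox.test(v, ref, exact = FALSE)$p.value
    }
    data.frame(group = g, n = length(v), median_h = stats::median(v),
               mean_h = mean(v), p_t = p_t, p_wilcox = p_w, tested = tested,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_t_BH <- NA_real_
  out$p_t_BH[out$tested] <- stats::p.adjust(out$p_t[out$tested], method = "BH")
  rownames(out) <- NULL
  attr(out, "settings") <- list(log_transform = log_transform,
                                var_equal = var_equal, min_n = min_n)
  out
}
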