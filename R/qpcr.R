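# qPCR delta-Ct analysis: normalisation against the geometric mean of
# two housekeeping genes, relative expression, and hand-off of
# untransformed delta-Ct values to the statistics engine.

#' Simulate a qPCR Cq table with known group structure
#'
#' Cq values are drawn from Normal(mean, sd) per sample and target. Each
#' group's `mean_cq` must include both housekeeping targets.
#'
#' @param groups list of group definitions: `list(name =, n =, mean_cq =
#'   named vector of per-target mean Cq, sd = )`; `n >= 2`, `sd >= 0`.
#' @param housekeeping exactly two housekeeping target names.
#' @param seed integer seed.
#' @return long-format data frame `sample, group, target, cq`.
#' @export
simulate_ct_table <- function(groups, housekeeping = c("Gapdh", "Actb"),
                              seed = 1) {
  stopifnot(length(housekeeping) == 2)
  set.seed(as.integer(seed))
  rows <- lapply(groups, function(g) {
    stopifnot(g$n >= 2, g$sd >= 0)
    if (!all(housekeeping %in% names(g$mean_cq)))
      stop("group '", g$name, "' lacks a housekeeping target mean")
    samples <- paste0(g$name, "_s", seq_len(g$n))
    do.call(rbind, lapply(names(g$mean_cq), function(tg)
      data.frame(sample = samples, group = g$name, target = tg,
                 cq = stats::rnorm(g$n, g$mean_cq[[tg]], g$sd))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delta-Ct normalisation against two housekeeping genes
#'
#' Technical replicates (repeated rows for one sample/target) are
#' averaged arithmetically, then each target's Cq is normalised by the
#' geometric mean of the two housekeeping Cq values of the same sample:
#' `dCt = Cq_target - sqrt(Cq_hk1 * Cq_hk2)`. Rows with missing Cq
#' (undetermined wells) are dropped with a warning.
#'
#' @param cq_table data frame with columns `sample`, `target`, `cq` and
#'   optionally `group`.
#' @param housekeeping exactly two housekeeping target names; both must
#'   be present for every sample.
#' @return data frame `sample, group, target, cq, hk_ref, delta_ct` with
#'   one row per sample and non-housekeeping target.
#' @examples
#' tab <- data.frame(sample = "s1", target = c("Acta2", "Gapdh", "Actb"),
#'                   cq = c(25, 20, 22))
#' delta_ct(tab)$delta_ct  # 25 - sqrt(440)
#' @export
delta_ct <- function(cq_table, housekeeping = c("Gapdh", "Actb")) {
  stopifnot(is.data.frame(cq_table),
            all(c("sample", "target", "cq") %in% names(cq_table)),
            length(housekeeping) == 2)
  if (!"group" %in% names(cq_table)) cq_table$group <- "all"
  if (anyNA(cq_table$cq)) {
    warning(sum(is.na(cq_table$cq)),
            " undetermined well(s) dropped before normalisation")
    cq_table <- cq_table[!is.na(cq_table$cq), ]
  }
  if (any(cq_table$cq <= 0)) stop("Cq values must be positive")
  avg <- stats::aggregate(cq ~ sample + group + target, cq_table, mean)
  hk <- avg[avg$target %in% housekeeping, ]
  hk_wide <- stats::reshape(hk, idvar = c("sample", "group"),
                            timevar = "target", direction = "wide")
  need <- paste0("cq.", housekeeping)
  missing_cols <- setdiff(need, names(hk_wide))
  if (length(missing_cols) || anyNA(hk_wide[, need])) {
    bad <- if (length(missing_cols)) unique(avg$sample)
           else hk_wide$sample[!stats::complete.cases(hk_wide[, need])]
    stop("missing housekeeping Cq (", paste(housekeeping, collapse = ", "),
         ") for sample(s): ", paste(bad, collapse = ", "))
  }
  hk_wide$hk_ref <- sqrt(hk_wide[[need[1]]] * hk_wide[[need[2]]])
  tg <- avg[!avg$target %in% housekeeping, ]
  miss <- setdiff(unique(tg$sample), hk_wide$sample)
  if (length(miss))
    stop("missing housekeeping Cq for sample(s): ", paste(miss, collapse = ", "))
  out <- merge(tg, hk_wide[, c("sample", "group", "hk_ref")],
               by = c("sample", "group"), sort = FALSE)
  out$delta_ct <- out$cq - out$hk_ref
  out[order(out$target, out$group, out$sample),
      c("sample", "group", "target", "cq", "hk_ref", "delta_ct")]
}

#' Relative expression (2^-ddCt) against a reference group
#'
#' ddCt is each sample's delta-Ct minus the mean delta-Ct of the
#' reference group for the same target; fold change is `2^-ddCt`
#' (amplification efficiency assumed 2). The reference group's mean fold
#' change is exactly 1 by construction. Group statistics should always
#' be computed on the untransformed delta-Ct values, not on fold
#' changes — use [stats_input()] for that.
#'
#' @param dct output of [delta_ct()].
#' @param reference reference group label.
#' @return `dct` with added `ddct` and `fold` columns.
#' @export
relative_expression <- function(dct, reference) {
  stopifnot(all(c("group", "target", "delta_ct") %in% names(dct)))
  if (!any(dct$group == reference))
    stop("reference group '", reference, "' is empty")
  ref_mean <- tapply(dct$delta_ct[dct$group == reference],
                     dct$target[dct$group == reference], mean)
  if (!all(unique(dct$target) %in% names(ref_mean)))
    stop("reference group lacks some targets")
  dct$ddct <- dct$delta_ct - as.numeric(ref_mean[dct$target])
  dct$fold <- 2^(-dct$ddct)
  dct
}

#' Group-wise delta-Ct values for the statistics engine
#'
#' Returns the untransformed delta-Ct values of one target split by
#' group, the form consumed by [select_test()] / [run_test()].
#'
#' @param dct output of [delta_ct()].
#' @param target target name; may be omitted when only one is present.
#' @return named list of numeric vectors, one per group.
#' @export
stats_input <- function(dct, target = NULL) {
  stopifnot(all(c("group", "target", "delta_ct") %in% names(dct)))
  tgs <- unique(dct$target)
  if (is.null(target)) {
    if (length(tgs) > 1)
      stop("multiple targets present; specify `target`")
    target <- tgs
  }
  sub <- dct[dct$target == target, ]
  groups <- split(sub$delta_ct, sub$group)
  if (length(groups) < 2)
    stop("at least two groups are required for a comparison")
  groups
}

#' Read a Cq table from CSV
#' @param path CSV with columns `sample, group, target, cq`.
#' @return data frame.
#' @export
read_cq <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("sample", "target", "cq") %in% names(df)))
    stop("Cq CSV needs columns sample, target, cq")
  df
}
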