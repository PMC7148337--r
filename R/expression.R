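# Microarray call processing: iterative correlation z-score sample QC,
# present/marginal/absent binarization with probe -> gene collapse, and
# per-gene ubiquity (expressed-state frequency) scores.

#' Remove outlier samples by iterative correlation z-score
#'
#' Per round: the Pearson correlation is computed between every pair of
#' samples; each sample's summary statistic is its mean correlation to all
#' others; z-scores of these means are taken (n-1 denominator sd) and every
#' sample with `|z| >= z_threshold` is removed. Rounds repeat until no
#' sample is removed. Samples with zero variance (constant profile) have an
#' undefined correlation and are removed with their own reason code.
#'
#' @param values numeric matrix, probes x samples, no missing values.
#' @param z_threshold removal cutoff on `|z|` (inclusive), default 2.
#' @param log2_transform correlate on `log2(x + 1)` of the values — use for
#'   raw-scale intensities.
#' @return list with `kept` (sample ids), `removed` (data.frame: sample,
#'   round, z, reason) and `rounds` — the full audit trail, one data.frame
#'   per round with each sample's mean correlation and z-score.
#' @export
remove_outlier_samples <- function(values, z_threshold = 2,
                                   log2_transform = FALSE) {
  stopifnot(is.matrix(values), !anyNA(values))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  if (ncol(values) < 3L) stop("need at least 3 samples for outlier QC")
  x <- if (log2_transform) log2(values + 1) else values

  kept <- colnames(x)
  removed <- data.frame(sample = character(0), round = integer(0),
                        z = numeric(0), reason = character(0),
                        stringsAsFactors = FALSE)
  rounds <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    sub <- x[, kept, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    if (any(sds == 0)) {
      flat <- kept[sds == 0]
      removed <- rbind(removed, data.frame(sample = flat, round = round_i,
                                           z = NA_real_,
                                           reason = "constant_profile"))
      kept <- setdiff(kept, flat)
      rounds[[round_i]] <- data.frame(sample = flat, mean_cor = NA_real_,
                                      z = NA_real_, removed = TRUE)
      if (length(kept) < 3L) break
      next
    }
    cc <- stats::cor(sub)
    xi <- (rowSums(cc) - 1) / (length(kept) - 1)   # mean correlation to others
    s <- stats::sd(xi)
    z <- if (s > 0) (xi - mean(xi)) / s else rep(0, length(xi))
    out <- abs(z) >= z_threshold
    rounds[[round_i]] <- data.frame(sample = kept, mean_cor = unname(xi),
                                    z = unname(z), removed = out,
                                    stringsAsFactors = FALSE)
    if (!any(out)) break
    removed <- rbind(removed, data.frame(sample = kept[out], round = round_i,
                                         z = unname(z[out]),
                                         reason = "correlation_outlier"))
    kept <- kept[!out]
    if (length(kept) < 3L) break
  }
  list(kept = kept, removed = removed, rounds = rounds)
}

#' Binarize P/M/A calls and collapse probes to genes
#'
#' "Present" becomes 1, "Marginal" and "Absent" become 0. Genes measured by
#' several probe sets take the per-sample maximum over their probes.
#' Probes absent from the probe map are dropped (their count is recorded in
#' the `"dropped_probes"` attribute).
#'
#' @param calls character matrix, probes x samples, entries in
#'   `c("P", "M", "A")`.
#' @param probe_map data.frame with columns `probe`, `gene`.
#' @return integer 0/1 matrix, genes x samples (a call matrix).
#' @export
binarize_and_collapse <- function(calls, probe_map) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)))
  probe_map <- as.data.frame(probe_map, stringsAsFactors = FALSE)
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  bad <- !(calls %in% c("P", "M", "A"))
  if (any(bad)) {
    w <- arrayInd(which(bad)[1L], dim(calls))
    stop(sprintf("unknown call symbol %s for probe %s, sample %s",
                 deparse(calls[w[1L, 1L], w[1L, 2L]]), rownames(calls)[w[1L, 1L]],
                 colnames(calls)[w[1L, 2L]]))
  }
  known <- rownames(calls) %in% probe_map$probe
  dropped <- sum(!known)
  calls <- calls[known, , drop = FALSE]
  bin <- (calls == "P") + 0L
  gene <- probe_map$gene[match(rownames(calls), probe_map$probe)]
  # max over a gene's probes = "any probe present"
  agg <- rowsum(bin, group = gene)
  out <- (agg > 0L) + 0L
  out <- out[order(rownames(out)), , drop = FALSE]
  storage.mode(out) <- "integer"
  attr(out, "dropped_probes") <- dropped
  out
}

#' Gene ubiquity scores
#'
#' The ubiquity (expressed-state frequency) of a gene is the fraction of
#' samples in which it is called expressed: the row mean of the call
#' matrix. Requested genes missing from the matrix (not on the platform)
#' get frequency 0 and are listed in a warning.
#'
#' @param calls 0/1 matrix, genes x samples (>= 1 sample).
#' @param genes optional character vector of genes to report (default: the
#'   matrix rows).
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
gene_ubiquity <- function(calls, genes = NULL) {
  stopifnot(is.matrix(calls), ncol(calls) >= 1L)
  u <- rowMeans(calls)
  if (is.null(genes)) return(u)
  out <- stats::setNames(numeric(length(genes)), genes)
  hit <- intersect(genes, names(u))
  out[hit] <- u[hit]
  miss <- setdiff(genes, names(u))
  if (length(miss))
    warning(length(miss), " gene(s) absent from the call matrix scored 0: ",
            paste(utils::head(miss, 5), collapse = ", "),
            if (length(miss) > 5) ", ...")
  out
}

#' Read a call matrix (P/M/A symbols) from TSV
#'
#' @param path TSV, probes in rows (first column = probe id), samples in
#'   columns.
#' @return character matrix.
#' @export
read_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
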