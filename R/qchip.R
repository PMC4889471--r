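signature_marks <- c("H3K27me3", "H3K9me3", "H3K9ac")

#' Summarize a five-primer serial qChIP series
#'
#' Per-primer mean and sample standard deviation (n - 1 denominator; sd 0
#' with a warning when only one replicate exists), ordered by primer offset
#' relative to the TSS.
#'
#' @param d \code{qchip_dataset} (see \code{\link{read_qchip_table}}).
#' @param gene,target,condition series key.
#' @return list of class \code{qchip_series_summary} with fields offsets,
#'   mean, sd, n_reps.
#' @export
summarize_series <- function(d, gene, target, condition) {
  rows <- d[d$gene == gene & d$target == target & d$condition == condition, ]
  if (!nrow(rows))
    stop(sprintf("no qChIP series for (%s, %s, %s)", gene, target, condition))
  offs <- sort(unique(rows$primer_offset))
  mu <- s <- numeric(length(offs))
  nr <- integer(length(offs))
  single <- FALSE
  for (i in seq_along(offs)) {
    v <- rows$enrichment[rows$primer_offset == offs[i]]
    mu[i] <- mean(v)
    nr[i] <- length(v)
    if (length(v) == 1) {
      s[i] <- 0
      single <- TRUE
    } else s[i] <- stats::sd(v)
  }
  if (single)
    warning(sprintf("single replicate in series (%s, %s, %s): sd set to 0",
                    gene, target, condition))
  structure(list(gene = gene, target = target, condition = condition,
                 offsets = offs, mean = mu, sd = s, n_reps = nr),
            class = "qchip_series_summary")
}

#' Per-position log2 fold change between two conditions
#'
#' \code{log2((treat + pseudocount) / (ctrl + pseudocount))} at each primer
#' position, clamped to \code{[-cap, cap]}. Ratios make the result
#' invariant to the (uninterpreted) enrichment unit. Accepts two series
#' summaries (primer offsets must match exactly) or two bare numeric
#' vectors of equal length.
#'
#' @param ctrl,treat \code{qchip_series_summary} objects or numeric mean
#'   vectors.
#' @param pseudocount added to both conditions, in enrichment units
#'   (default 0.01).
#' @param cap maximum |log2 fold change| (default 8).
#' @return numeric vector of log2 fold changes, with the primer offsets as
#'   the \code{"offsets"} attribute when known.
#' @export
compare_conditions <- function(ctrl, treat, pseudocount = 0.01, cap = 8) {
  offs <- NULL
  if (inherits(ctrl, "qchip_series_summary") &&
      inherits(treat, "qchip_series_summary")) {
    if (!identical(ctrl$offsets, treat$offsets))
      stop("mismatched primer offsets between conditions")
    offs <- ctrl$offsets
    c_mu <- ctrl$mean; t_mu <- treat$mean
  } else {
    c_mu <- as.numeric(ctrl); t_mu <- as.numeric(treat)
    if (length(c_mu) != length(t_mu))
      stop("mismatched series lengths between conditions")
  }
  lfc <- log2((t_mu + pseudocount) / (c_mu + pseudocount))
  lfc <- pmax(pmin(lfc, cap), -cap)
  if (!is.null(offs)) attr(lfc, "offsets") <- offs
  lfc
}

#' Call a per-mark change from five log2 fold changes
#'
#' The series summary is the median of the five per-primer log2 fold
#' changes (robust to one outlying primer pair); the call is INCREASED when
#' the median is at least \code{+threshold}, DECREASED at or below
#' \code{-threshold}, UNCHANGED otherwise.
#'
#' @param log2fc numeric vector of finite per-position log2 fold changes.
#' @param threshold call threshold in log2 units (default 1).
#' @param mark optional mark label carried through.
#' @return list of class \code{change_call} with fields mark,
#'   per_position_log2fc, summary_log2fc, call, threshold.
#' @export
call_change <- function(log2fc, threshold = 1, mark = NULL) {
  if (!all(is.finite(log2fc))) stop("non-finite log2 fold change")
  m <- stats::median(log2fc)
  call <- if (m >= threshold) "INCREASED"
          else if (m <= -threshold) "DECREASED"
          else "UNCHANGED"
  structure(list(mark = mark, per_position_log2fc = as.numeric(log2fc),
                 summary_log2fc = m, call = call, threshold = threshold),
            class = "change_call")
}

#' Classify the epigenetic repression signature of a gene
#'
#' Truth table over the three informative marks' change calls:
#' \itemize{
#'   \item H3K27me3 UNCHANGED, H3K9me3 INCREASED, H3K9ac DECREASED ->
#'     \code{IKAROS_ONLY} (direct factor binding: heterochromatin via
#'     H3K9me3 gain and H3K9ac loss);
#'   \item H3K27me3 INCREASED, H3K9me3 UNCHANGED, H3K9ac DECREASED ->
#'     \code{IKAROS_HDAC1} (HDAC1 recruitment: H3K27me3 gain with H3K9ac
#'     loss);
#'   \item all three UNCHANGED -> \code{NONE};
#'   \item any other combination -> \code{AMBIGUOUS}.
#' }
#'
#' @param calls named list of \code{change_call}s (or a named character
#'   vector of calls) containing entries H3K27me3, H3K9me3, H3K9ac.
#' @return list of class \code{signature_call} with fields label and calls.
#' @export
classify_signature <- function(calls) {
  get_call <- function(m) {
    x <- calls[[m]]
    if (is.null(x)) stop("missing change call for mark ", m)
    if (inherits(x, "change_call")) x$call else as.character(x)
  }
  k27 <- get_call("H3K27me3")
  k9me <- get_call("H3K9me3")
  k9ac <- get_call("H3K9ac")
  label <-
    if (k27 == "UNCHANGED" && k9me == "INCREASED" && k9ac == "DECREASED")
      "IKAROS_ONLY"
    else if (k27 == "INCREASED" && k9me == "UNCHANGED" && k9ac == "DECREASED")
      "IKAROS_HDAC1"
    else if (k27 == "UNCHANGED" && k9me == "UNCHANGED" && k9ac == "UNCHANGED")
      "NONE"
    else "AMBIGUOUS"
  structure(list(label = label,
                 calls = c(H3K27me3 = k27, H3K9me3 = k9me, H3K9ac = k9ac)),
            class = "signature_call")
}

#' Call repression signatures for every gene in a qChIP dataset
#'
#' For each gene, summarizes the control and treated series of each
#' measured target, computes per-mark change calls, and classifies the
#' three-mark signature. A factor (IK) series, when present, gates
#' interpretation: \code{ikaros_dependent} is TRUE only when the IK series
#' itself is called INCREASED (binding restored/increased in the treated
#' condition). H3K4me3 series are summarized but excluded from
#' classification.
#'
#' @param d \code{qchip_dataset}.
#' @param ctrl,treat condition labels to compare.
#' @param threshold,pseudocount,cap see \code{\link{call_change}} and
#'   \code{\link{compare_conditions}}.
#' @return data.frame with one row per gene: per-mark summary log2 fold
#'   changes and calls, signature label, and ikaros_dependent.
#' @export
call_signatures <- function(d, ctrl, treat, threshold = 1,
                            pseudocount = 0.01, cap = 8) {
  stopifnot(inherits(d, "qchip_dataset"))
  for (cond in c(ctrl, treat))
    if (!cond %in% d$condition)
      stop("condition not present in dataset: ", cond)
  genes <- unique(d$gene)
  rows <- lapply(genes, function(g) {
    targets <- unique(d$target[d$gene == g])
    ch <- list()
    for (tg in targets) {
      s_c <- summarize_series(d, g, tg, ctrl)
      s_t <- summarize_series(d, g, tg, treat)
      lfc <- compare_conditions(s_c, s_t, pseudocount, cap)
      ch[[tg]] <- call_change(lfc, threshold, mark = tg)
    }
    miss <- setdiff(signature_marks, names(ch))
    if (length(miss))
      stop(sprintf("gene %s: missing series for %s", g,
                   paste(miss, collapse = ", ")))
    sig <- classify_signature(ch[signature_marks])
    ik_dep <- "IK" %in% names(ch) && ch[["IK"]]$call == "INCREASED"
    out <- data.frame(gene = g, label = sig$label,
                      ikaros_dependent = ik_dep, stringsAsFactors = FALSE)
    for (m in names(ch)) {
      out[[paste0("lfc_", m)]] <- ch[[m]]$summary_log2fc
      out[[paste0("call_", m)]] <- ch[[m]]$call
    }
    out
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
    r[cols]
  })
  do.call(rbind, rows)
}
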