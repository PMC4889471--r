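#' Read a BED3/BED6/narrowPeak peak file
#'
#' Accepts exactly three dialects: BED3 (chrom, start, end), BED6 (+ name,
#' score, strand) and 10-column ENCODE narrowPeak (BED6 + signalValue,
#' pValue, qValue, summit offset). Any other column count, a non-integer or
#' inverted coordinate, is a hard error naming the offending line.
#' \code{track}, \code{browser}, comment and blank lines are skipped and
#' their count reported via \code{message()}.
#'
#' @param path file path.
#' @param label optional set label attached as metadata.
#' @param genome optional named chromosome-length vector.
#' @return sorted GRanges; narrowPeak extras kept as metadata columns
#'   \code{signal}, \code{pvalue}, \code{qvalue}, \code{summit}.
#' @export
read_bed <- function(path, label = NULL, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  skip <- grepl("^#", lines) | grepl("^(track|browser)([ \t]|$)", lines) |
    grepl("^[ \t]*$", lines)
  if (any(skip))
    message("read_bed: skipped ", sum(skip),
            " comment/track/blank line(s) in ", path)
  lineno <- which(!skip)
  body <- lines[!skip]
  if (!length(body))
    return(peak_set(character(), integer(), integer(),
                    label = label, genome = genome))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!nf %in% c(3L, 6L, 10L))
  if (length(bad))
    stop("line ", lineno[bad[1]], ": ", nf[bad[1]],
         " columns (expected 3, 6 or 10)")
  col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  chrom <- col(1)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop("line ", lineno[bad[1]], ": non-integer start/end")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("line ", lineno[bad[1]], ": invalid interval (start >= end or < 0)")
  name <- score <- strand <- NULL
  if (any(nf >= 6)) {
    name <- col(4)
    score <- suppressWarnings(as.numeric(col(5)))
    strand <- col(6)
    strand[is.na(strand)] <- "."
    bad <- which(!strand %in% c("+", "-", "."))
    if (length(bad))
      stop("line ", lineno[bad[1]], ": bad strand '", strand[bad[1]], "'")
  }
  gr <- peak_set(chrom, start, end, strand = strand, name = name,
                 score = score, label = label, genome = genome)
  if (any(nf == 10)) {
    # peak_set() sorts, so recompute the permutation to align extras
    o <- order(match(chrom, GenomeInfoDb::seqlevels(gr)), start, end)
    mcols(gr)$signal <- suppressWarnings(as.numeric(col(7)))[o]
    mcols(gr)$pvalue <- suppressWarnings(as.numeric(col(8)))[o]
    mcols(gr)$qvalue <- suppressWarnings(as.numeric(col(9)))[o]
    smt <- suppressWarnings(as.integer(col(10)))[o]
    mcols(gr)$summit <- smt
  }
  gr
}

#' Write a peak set as BED6
#'
#' Emits a single "#" header comment (pipeline version and label) followed
#' by BED6 rows in 0-based half-open coordinates. \code{read_bed()} on the
#' result reproduces the BED6 content exactly.
#'
#' @param p GRanges.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_bed <- function(p, path) {
  df <- as_bed_frame(p)
  if (is.null(df$name)) df$name <- rep(".", nrow(df))
  df$name[is.na(df$name)] <- "."
  if (is.null(df$score)) df$score <- rep(0, nrow(df))
  df$score[is.na(df$score)] <- 0
  hdr <- sprintf("# chromsig %s | label=%s | n=%d",
                 as.character(utils::packageVersion("chromsig")),
                 if (is.null(peak_label(p))) "." else peak_label(p),
                 length(p))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(df))
    writeLines(paste(df$chrom, format_coord(df$start), format_coord(df$end),
                     df$name, df$score, df$strand, sep = "\t"), con)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a gene annotation (TSS table or gene-level GTF)
#'
#' Two dialects: a tab-delimited table with header columns
#' \code{gene_id, chrom, strand, start, end} (0-based half-open,
#' optional \code{gene_name}), or GTF lines of which only feature
#' \code{"gene"} rows are used (1-based inclusive, converted on read).
#' The TSS is derived from the gene span: the first covered base for "+"
#' genes (\code{start}), the last covered base for "-" genes
#' (\code{end - 1}). Strand is required; duplicate gene_ids are an error.
#'
#' @param path file path.
#' @return data.frame of class \code{gene_annotation} with columns gene_id,
#'   gene_name, chrom, strand, tss, gene_start, gene_end (0-based).
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^[ \t]*$", lines)]
  if (!length(lines)) stop("empty annotation file: ", path)
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if ("gene_id" %in% first) {
    df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "start", "end")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("annotation missing column(s): ", paste(miss, collapse = ", "))
    if (!"gene_name" %in% names(df)) df$gene_name <- df$gene_id
    ann <- data.frame(gene_id = as.character(df$gene_id),
                      gene_name = as.character(df$gene_name),
                      chrom = as.character(df$chrom),
                      strand = as.character(df$strand),
                      gene_start = as.numeric(df$start),
                      gene_end = as.numeric(df$end),
                      stringsAsFactors = FALSE)
  } else if (length(first) == 9) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(f, function(x) x[3] == "gene", logical(1))
    f <- f[keep]
    if (!length(f)) stop("no feature-'gene' rows in GTF: ", path)
    attr_field <- vapply(f, `[`, character(1), 9)
    get_attr <- function(key) {
      m <- regmatches(attr_field,
                      regexpr(paste0(key, ' "[^"]*"'), attr_field))
      out <- rep(NA_character_, length(attr_field))
      hit <- grepl(paste0(key, ' "'), attr_field)
      out[hit] <- sub(paste0(key, ' "([^"]*)"'), "\\1",
                      regmatches(attr_field,
                                 regexpr(paste0(key, ' "[^"]*"'),
                                         attr_field)))
      out
    }
    gid <- get_attr("gene_id")
    if (anyNA(gid)) stop("GTF gene row without gene_id attribute")
    gname <- get_attr("gene_name")
    gname[is.na(gname)] <- gid[is.na(gname)]
    ann <- data.frame(gene_id = gid, gene_name = gname,
                      chrom = vapply(f, `[`, character(1), 1),
                      strand = vapply(f, `[`, character(1), 7),
                      # GTF is 1-based inclusive -> 0-based half-open
                      gene_start = as.numeric(vapply(f, `[`, character(1), 4)) - 1,
                      gene_end = as.numeric(vapply(f, `[`, character(1), 5)),
                      stringsAsFactors = FALSE)
  } else {
    stop("unrecognized annotation format (need TSS table header or GTF)")
  }
  if (anyNA(ann$gene_start) || anyNA(ann$gene_end))
    stop("non-numeric gene coordinates")
  if (any(ann$gene_start < 0 | ann$gene_start >= ann$gene_end))
    stop("invalid gene span (start >= end)")
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene (required for TSS)")
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  ann$tss <- ifelse(ann$strand == "+", ann$gene_start, ann$gene_end - 1)
  ann <- ann[, c("gene_id", "gene_name", "chrom", "strand", "tss",
                 "gene_start", "gene_end")]
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read a serial qChIP measurement table
#'
#' CSV with columns \code{gene, target, condition, primer_index,
#' primer_offset, enrichment, replicate}. Every (gene, target, condition)
#' series must have exactly 5 distinct primer indices; negative enrichment
#' or a missing condition label is a hard error. Enrichment units (percent
#' input vs fold over control antibody) are deliberately not interpreted:
#' downstream comparisons use ratios between conditions only.
#'
#' @param path CSV file path.
#' @return data.frame of class \code{qchip_dataset}.
#' @export
read_qchip_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_qchip(df)
}

validate_qchip <- function(df) {
  need <- c("gene", "target", "condition", "primer_index", "primer_offset",
            "enrichment", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("qChIP table missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(df$condition) | df$condition == ""))
    stop("missing condition label in qChIP table")
  if (any(is.na(df$enrichment) | df$enrichment < 0))
    stop("negative or missing enrichment in qChIP table")
  key <- paste(df$gene, df$target, df$condition, sep = " / ")
  nprim <- tapply(df$primer_index, key, function(x) length(unique(x)))
  bad <- names(nprim)[nprim != 5]
  if (length(bad))
    stop("series with != 5 primer pairs: ", bad[1])
  class(df) <- c("qchip_dataset", "data.frame")
  df
}

#' Write / read a generic TSV with a provenance header
#'
#' Writers in this package emit one "#"-prefixed comment line carrying the
#' package version and any parameters, then a tab-separated table with a
#' header row. \code{read_tsv_table()} re-parses such files.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param params optional named list recorded in the header comment.
#' @return invisibly, \code{path}.
#' @export
write_tsv_table <- function(df, path, params = NULL) {
  hdr <- sprintf("# chromsig %s%s",
                 as.character(utils::packageVersion("chromsig")),
                 if (length(params))
                   paste0(" | ", paste(names(params), unlist(params),
                                       sep = "=", collapse = " ")) else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Report chromosome-name mismatches between annotation and peak sets
#'
#' Chromosome names are taken verbatim everywhere; this check surfaces
#' "chr1" vs "1" style disagreements before they silently produce empty
#' overlaps.
#'
#' @param ann gene_annotation.
#' @param ... one or more GRanges peak sets.
#' @return character vector of messages; empty when the name sets agree.
#' @export
check_chromosome_names <- function(ann, ...) {
  ref <- unique(ann$chrom)
  out <- character()
  sets <- list(...)
  for (i in seq_along(sets)) {
    have <- unique(as.character(GenomicRanges::seqnames(sets[[i]])))
    extra <- setdiff(have, ref)
    if (length(extra))
      out <- c(out, paste0("peak set ", i, ": chromosomes not in annotation: ",
                           paste(extra, collapse = ", ")))
  }
  out
}

# genome.tsv: two columns, chrom and length, no header comment required
read_genome_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$length), df$chrom)
}

write_genome_table <- function(genome, path) {
  write_tsv_table(data.frame(chrom = names(genome),
                             length = format_coord(unname(genome))), path)
}
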