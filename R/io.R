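#' Read a SEG-style segment table
#'
#' Parses a tab-delimited CBS segment file with the six standard columns
#' `sample`, `chrom`, `loc.start`, `loc.end`, `num.info`, `seg.mean`
#' (header names are matched case-insensitively and `.`/`_` are
#' interchangeable). On-disk coordinates are 1-based inclusive, the
#' convention of SEG files; they are converted to the package-internal
#' 0-based half-open convention at this boundary and nowhere else.
#'
#' @param path path to a tab-delimited SEG file.
#' @return a `data.frame` with columns `sample`, `chrom`, `start`, `end`
#'   (0-based half-open), `num_info`, `seg_mean`.
#' @export
read_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- normalize_seg_names(names(df))
  required <- c("sample", "chrom", "loc_start", "loc_end", "num_info", "seg_mean")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_input("segment file %s is missing column(s): %s",
               path, paste(missing_cols, collapse = ", "))
  }
  for (col in c("loc_start", "loc_end", "num_info", "seg_mean")) {
    vals <- df[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      stop_input("segment file %s line %d: non-numeric %s value '%s'",
                 path, bad[1] + 1L, col, as.character(vals[bad[1]]))
    }
    df[[col]] <- num
  }
  out <- data.frame(
    sample   = as.character(df$sample),
    chrom    = as.character(df$chrom),
    start    = df$loc_start - 1,
    end      = df$loc_end,
    num_info = as.integer(df$num_info),
    seg_mean = df$seg_mean,
    stringsAsFactors = FALSE
  )
  validate_segments(out, path)
  out
}

normalize_seg_names <- function(x) {
  x <- tolower(gsub("[.\\s]", "_", x, perl = TRUE))
  x[x %in% c("id", "sample_id")] <- "sample"
  x[x %in% c("chromosome", "chr")] <- "chrom"
  x[x == "start"] <- "loc_start"
  x[x == "end"] <- "loc_end"
  x[x %in% c("num_mark", "num_probes")] <- "num_info"
  x
}

validate_segments <- function(seg, origin = "segments") {
  if (nrow(seg) == 0) return(invisible(seg))
  if (any(seg$start >= seg$end)) {
    stop_input("%s: segment with start >= end", origin)
  }
  if (any(seg$num_info < 1)) {
    stop_input("%s: segment with num_info < 1", origin)
  }
  if (any(!is.finite(seg$seg_mean))) {
    stop_input("%s: non-finite seg.mean", origin)
  }
  invisible(seg)
}

#' Write a SEG-style segment table
#'
#' Inverse of [read_segments()]: internal 0-based half-open coordinates are
#' converted back to the 1-based inclusive on-disk convention.
#'
#' @param segments data.frame as returned by [read_segments()].
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(
    sample     = segments$sample,
    chrom      = segments$chrom,
    loc.start  = format_num(segments$start + 1),
    loc.end    = format_num(segments$end),
    num.info   = segments$num_info,
    seg.mean   = format_num(segments$seg_mean),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write_tsv(out, path)
  invisible(path)
}

#' Read a genes-by-samples numeric matrix
#'
#' First column holds gene identifiers, the header row holds sample
#' identifiers. `NA` cells become missing values (never zero). For the
#' methylation `beta` dialect, values are validated against \[0, 1\].
#'
#' @param path TSV path.
#' @param modality one of `"cnv"`, `"methylation"`, `"expression"`.
#' @param dialect methylation dialect, `"moma_ratio"` or `"beta"`; only
#'   consulted when `modality == "methylation"`.
#' @param sample_groups optional data.frame from [read_sample_groups()];
#'   every matrix column must then be a known sample.
#' @return numeric matrix with gene rownames and sample colnames;
#'   attributes `modality` and (when given) `sample_group`.
#' @export
read_matrix <- function(path, modality = c("cnv", "methylation", "expression"),
                        dialect = c("moma_ratio", "beta"),
                        sample_groups = NULL) {
  modality <- match.arg(modality)
  dialect <- match.arg(dialect)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop_input("matrix file %s needs a gene column plus samples", path)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop_input("matrix file %s: duplicate gene id '%s'",
               path, genes[duplicated(genes)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    m2 <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
    # cells that were not NA in text but failed conversion are format errors
    bad <- which(is.na(m2) & !(m == "NA" | is.na(m)), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop_input("matrix file %s line %d: non-numeric value '%s'",
                 path, bad[1, 1] + 1L, m[bad[1, 1], bad[1, 2]])
    }
    m <- m2
    colnames(m) <- colnames(df)[-1]
  }
  rownames(m) <- genes
  if (modality == "methylation" && dialect == "beta") {
    vals <- m[!is.na(m)]
    if (any(vals < 0 | vals > 1)) {
      stop_input("matrix file %s: beta values must lie in [0, 1]", path)
    }
  }
  attr(m, "modality") <- modality
  if (!is.null(sample_groups)) {
    unknown <- setdiff(colnames(m), sample_groups$sample_id)
    if (length(unknown) > 0) {
      stop_input("matrix file %s: sample '%s' absent from sample groups",
                 path, unknown[1])
    }
    attr(m, "sample_group") <- setNames(
      sample_groups$group[match(colnames(m), sample_groups$sample_id)],
      colnames(m)
    )
  }
  m
}

#' Write a genes-by-samples matrix as TSV
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param id_column header name of the gene-id column.
#' @export
write_matrix <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), apply(m, 2, format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(m))
  write_tsv(df, path)
  invisible(path)
}

#' Read a BED gene annotation
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged. Columns beyond the first six are
#' ignored; a missing strand column becomes `"."`.
#'
#' @param path BED path (chrom, start, end, name, \[score\], \[strand\]).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 4)) {
    stop_input("BED file %s line %d: fewer than 4 fields", path, which(n < 4)[1])
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (any(is.na(start)) || any(is.na(end))) {
    stop_input("BED file %s line %d: non-numeric coordinate",
               path, which(is.na(start) | is.na(end))[1])
  }
  strand <- if (all(n >= 6)) get(6) else rep(".", length(lines))
  strand[!strand %in% c("+", "-", ".")] <- "."
  ann <- data.frame(gene_id = get(4), chrom = get(1), start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE)
  validate_annotation(ann, path)
  ann
}

validate_annotation <- function(ann, origin = "annotation") {
  if (any(ann$start >= ann$end)) {
    stop_input("%s: interval with start >= end (line %d)",
               origin, which(ann$start >= ann$end)[1])
  }
  if (anyDuplicated(ann$gene_id)) {
    stop_input("%s: duplicate gene id '%s'",
               origin, ann$gene_id[duplicated(ann$gene_id)][1])
  }
  invisible(ann)
}

#' Write a gene annotation as BED
#' @param annotation data.frame as from [read_bed()].
#' @param path output path.
#' @export
write_bed <- function(annotation, path) {
  df <- data.frame(
    annotation$chrom, format_num(annotation$start), format_num(annotation$end),
    annotation$gene_id, 0L,
    if (is.null(annotation$strand)) "." else annotation$strand,
    stringsAsFactors = FALSE
  )
  writeLines(do.call(paste, c(df, sep = "\t")), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT path.
#' @return named list of character vectors of member genes; each element
#'   carries its description as attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_input("GMT file %s line %d: a set needs id, description and >= 1 member",
                 path, i)
    }
    members <- unique(fields[-(1:2)])
    attr(members, "description") <- fields[2]
    sets[[fields[1]]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#' @param gene_sets named list of character vectors (optionally with a
#'   `"description"` attribute each).
#' @param path output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(id) {
    members <- gene_sets[[id]]
    desc <- attr(members, "description") %||% ""
    paste(c(id, desc, as.character(members)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-group table
#'
#' Two tab-separated columns: `sample_id` and `group`, the latter either
#' `"tumor"` or `"normal"`.
#'
#' @param path TSV path.
#' @return data.frame with `sample_id`, `group`.
#' @export
read_sample_groups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop_input("sample group file %s needs columns sample_id, group", path)
  }
  bad <- setdiff(unique(df$group), c("tumor", "normal"))
  if (length(bad) > 0) {
    stop_input("sample group file %s: unknown group '%s'", path, bad[1])
  }
  df[c("sample_id", "group")]
}

#' @rdname read_sample_groups
#' @param groups data.frame with `sample_id`, `group`.
#' @export
write_sample_groups <- function(groups, path) {
  write_tsv(groups[c("sample_id", "group")], path)
  invisible(path)
}

# Deterministic TSV writer used for every artifact; fixed numeric
# formatting keeps reruns byte-identical.
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], format_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

format_num <- function(x) {
  if (!is.numeric(x)) return(x)
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- "NA"
  out
}
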