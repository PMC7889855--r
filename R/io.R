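## Readers/writers for the plain-text dialects the pipeline exchanges:
## BED3+ peaks and LD blocks, 7-column BEDPE loops, a gene TSV, and
## feature-by-sample count matrices. All readers validate and report the
## offending line number rather than coercing silently.

read_lines_table <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- vapply(fields, length, 1L)
  if (any(nc < n_min_cols)) {
    stop(what, ": line ", which(nc < n_min_cols)[1], " has ",
         nc[nc < n_min_cols][1], " column(s), need >= ", n_min_cols)
  }
  fields
}

parse_coord <- function(x, path, lines, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad)) {
    stop(what, " (", path, "): non-integer coordinate at line ",
         lines[which(bad)[1]])
  }
  v
}

#' Read a BED3+ file of peaks or LD blocks
#'
#' Columns: chrom, start, end and optionally a name (used as `name`;
#' for LD blocks the name is the lead-SNP label). Coordinates are 0-based
#' half-open as in the BED standard.
#'
#' @param path file path.
#' @param sample_id optional sample label attached to every record.
#' @return data.frame with `chrom`, `start`, `end`, `name` (NA when absent)
#'   and, when given, `sample_id`.
#' @export
read_bed <- function(path, sample_id = NULL) {
  fields <- read_lines_table(path, 3L, "BED")
  n <- length(fields)
  ln <- seq_len(n)
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = parse_coord(vapply(fields, `[`, "", 2L), path, ln, "BED"),
    end = parse_coord(vapply(fields, `[`, "", 3L), path, ln, "BED"),
    name = vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, ""),
    stringsAsFactors = FALSE)
  bad <- df$start >= df$end | df$start < 0
  if (any(bad)) stop("BED (", path, "): start >= end at line ", ln[which(bad)[1]])
  if (!is.null(sample_id)) df$sample_id <- sample_id
  df
}

#' Read LD blocks from BED4
#'
#' @inheritParams read_bed
#' @return data.frame `chrom`, `start`, `end`, `lead_snp`.
#' @export
read_ld_blocks <- function(path) {
  df <- read_bed(path)
  if (anyNA(df$name)) stop("LD-block BED (", path, "): missing lead-SNP name column")
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             lead_snp = df$name, stringsAsFactors = FALSE)
}

#' Read loops from 7-column BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, read_support
#' (and optionally group_id as column 8). Anchors are stored in canonical
#' order, sorted by (chrom, start, end).
#'
#' @param path file path.
#' @param group_id default group label when the file has no column 8.
#' @return data.frame `chrom1,start1,end1,chrom2,start2,end2,read_support,group_id`.
#' @export
read_bedpe <- function(path, group_id = "all") {
  fields <- read_lines_table(path, 7L, "BEDPE")
  ln <- seq_along(fields)
  get <- function(i) vapply(fields, `[`, "", i)
  df <- data.frame(
    chrom1 = get(1L),
    start1 = parse_coord(get(2L), path, ln, "BEDPE"),
    end1 = parse_coord(get(3L), path, ln, "BEDPE"),
    chrom2 = get(4L),
    start2 = parse_coord(get(5L), path, ln, "BEDPE"),
    end2 = parse_coord(get(6L), path, ln, "BEDPE"),
    stringsAsFactors = FALSE)
  rs <- suppressWarnings(as.numeric(get(7L)))
  bad <- is.na(rs) | rs < 0 | rs != floor(rs)
  if (any(bad)) stop("BEDPE (", path, "): bad read_support at line ", ln[which(bad)[1]])
  df$read_support <- as.integer(rs)
  df$group_id <- if (any(vapply(fields, length, 1L) >= 8L)) {
    vapply(fields, function(f) if (length(f) >= 8L) f[8L] else group_id, "")
  } else group_id
  bad <- df$start1 >= df$end1 | df$start2 >= df$end2 | df$start1 < 0 | df$start2 < 0
  if (any(bad)) stop("BEDPE (", path, "): start >= end at line ", ln[which(bad)[1]])
  canonicalize_loops(df)
}

## Anchor order within a loop is meaningless; store (chrom,start,end)-sorted.
canonicalize_loops <- function(loops) {
  if (nrow(loops) == 0L) return(loops)
  flip <- loops$chrom1 > loops$chrom2 |
    (loops$chrom1 == loops$chrom2 & (loops$start1 > loops$start2 |
      (loops$start1 == loops$start2 & loops$end1 > loops$end2)))
  if (any(flip)) {
    tmp <- loops[flip, c("chrom1", "start1", "end1")]
    loops[flip, c("chrom1", "start1", "end1")] <- loops[flip, c("chrom2", "start2", "end2")]
    loops[flip, c("chrom2", "start2", "end2")] <- tmp
  }
  rownames(loops) <- NULL
  loops
}

#' Read a gene annotation table
#'
#' Tab-separated with header: gene_id, chrom, start, end, strand.
#' The TSS is derived from strand: `start` for `+`, `end - 1` for `-`
#' (0-based half-open span).
#'
#' @param path file path.
#' @return data.frame `gene_id, chrom, start, end, strand, tss`.
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table (", path, "): missing column(s) ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("gene table (", path, "): duplicate gene_id")
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene table (", path, "): strand must be + or - at line ",
         which(!df$strand %in% c("+", "-"))[1] + 1L)
  }
  validate_intervals(df, "gene span")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
}

#' Read a feature-by-sample count matrix
#'
#' Tab-separated; header row of sample ids, first column of feature ids.
#'
#' @param path file path.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count matrix (", path, "): need id column + >=1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("count matrix (", path, "): duplicate feature id '",
         ids[anyDuplicated(ids)], "'")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
    stop("count matrix (", path, "): counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname read_bed
#' @param df table to write (BED columns, optional `name`).
#' @export
write_bed <- function(df, path) {
  cols <- df[, c("chrom", "start", "end"), drop = FALSE]
  if ("lead_snp" %in% names(df)) cols$name <- df$lead_snp
  else if ("name" %in% names(df) && !all(is.na(df$name))) cols$name <- df$name
  else if ("support" %in% names(df)) cols$name <- df$support
  write.table(format_coords(cols), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_bedpe
#' @param loops loop data.frame to write.
#' @export
write_bedpe <- function(loops, path) {
  cols <- loops[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                    "read_support", "group_id"), drop = FALSE]
  write.table(format_coords(cols), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_count_matrix
#' @param m matrix to write.
#' @param id_col header for the feature-id column.
#' @export
write_count_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic result table as TSV
#'
#' @param rows data.frame.
#' @param path file path.
#' @export
write_table <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## integer-format coordinate columns so write.table never emits 1e+05
format_coords <- function(df) {
  for (nm in intersect(names(df), c("start", "end", "start1", "end1", "start2", "end2"))) {
    df[[nm]] <- sprintf("%d", as.integer(df[[nm]]))
  }
  df
}
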