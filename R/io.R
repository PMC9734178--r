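## Readers/writers for the plain-text formats the pipeline touches.
## narrowPeak (ENCODE BED6+4), BED6, gene tables (TSV or a GFF3 gene subset),
## OrthoFinder Orthogroups.tsv, and a per-site variant-panel TSV.
## All coordinates are kept 0-based half-open internally.

#' Read an ENCODE narrowPeak (BED6+4) or BED6 file
#'
#' Accepts 6-10 tab-separated columns. Ten-column files populate the summit
#' offset from column 10; shorter files get the UCSC missing-value convention
#' (`-1`). Signal fold-change is taken from column 7 when present, otherwise
#' from the BED score column. An optional 11th column, written by
#' [write_narrowpeak()] when IDR values are attached, carries the IDR.
#'
#' @param path path to the file.
#' @return A data.frame with one row per peak, in file order: `chrom`, `start`,
#'   `end` (0-based half-open), `name`, `score`, `strand`, `signal_fc`,
#'   `pvalue_neglog10`, `qvalue_neglog10`, `summit_offset`, `idr` (`NA` when
#'   absent).
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t350\tp1\t0\t.\t8.5\t-1\t-1\t125", f)
#' read_narrowpeak(f)
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      signal_fc = numeric(), pvalue_neglog10 = numeric(),
                      qvalue_neglog10 = numeric(), summit_offset = integer(),
                      idr = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L | nf > 11L)
  if (length(bad))
    stop("malformed narrowPeak line(s) (expected 6-11 columns): ",
         paste(bad, collapse = ", "))
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  df <- data.frame(
    chrom  = get(1L),
    start  = as.integer(get(2L)),
    end    = as.integer(get(3L)),
    name   = get(4L),
    score  = as.numeric(get(5L)),
    strand = get(6L),
    signal_fc       = suppressWarnings(as.numeric(get(7L, "0"))),
    pvalue_neglog10 = suppressWarnings(as.numeric(get(8L, "-1"))),
    qvalue_neglog10 = suppressWarnings(as.numeric(get(9L, "-1"))),
    summit_offset   = suppressWarnings(as.integer(get(10L, "-1"))),
    idr             = suppressWarnings(as.numeric(get(11L, NA_character_))),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end)
  if (length(bad))
    stop("invalid interval (start >= end or non-numeric) at line(s): ",
         paste(bad, collapse = ", "))
  bad <- which(df$summit_offset != -1L &
               (df$summit_offset < 0L | df$summit_offset >= df$end - df$start))
  if (length(bad))
    stop("summit offset outside the peak interval at line(s): ",
         paste(bad, collapse = ", "))
  if (any(df$signal_fc < 0, na.rm = TRUE))
    stop("negative signal fold-change at line(s): ",
         paste(which(df$signal_fc < 0), collapse = ", "))
  df
}

#' Write peaks as narrowPeak
#'
#' Emits tab-separated 10-column narrowPeak; an 11th IDR column is appended
#' only when any peak carries a non-missing IDR. Reading a well-formed
#' 10-column file and writing it back is byte-identical.
#'
#' @param peaks a peak data.frame as returned by [read_narrowpeak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  cols <- cbind(peaks$chrom, peaks$start, peaks$end, peaks$name,
                .num_chr(peaks$score), peaks$strand, .num_chr(peaks$signal_fc),
                .num_chr(peaks$pvalue_neglog10), .num_chr(peaks$qvalue_neglog10),
                peaks$summit_offset)
  if (!is.null(peaks$idr) && any(!is.na(peaks$idr)))
    cols <- cbind(cols, .num_chr(peaks$idr))
  writeLines(apply(cols, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a gene-model table
#'
#' Two dialects are supported. `"tsv"` expects columns `gene_id`, `chrom`,
#' `tss`, `strand` (TSS already 0-based) plus any optional annotation columns
#' (`species`, `category`, `is_deg`, `is_down`, `log2fc_expr`, `fpkm_wt`).
#' `"gff3-subset"` reads `gene` features from a GFF3 file and converts the
#' 1-based coordinates to a 0-based TSS honouring strand: TSS = start - 1 on
#' `+`, end - 1 on `-`.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"gff3-subset"`.
#' @return data.frame of gene records with a 0-based `tss`.
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3-subset")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    .stopifnot_cols(df, c("gene_id", "chrom", "tss", "strand"), "gene table")
    df$tss <- as.integer(df$tss)
    for (col in c("is_deg", "is_down"))
      if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, function(f) length(f) >= 9L && f[[3]] == "gene", TRUE)
    fields <- fields[keep]
    if (!length(fields)) stop("no gene features found in ", path)
    ids <- vapply(fields, function(f) {
      m <- regmatches(f[[9]], regexec("(?:^|;)ID=([^;]+)", f[[9]]))[[1]]
      if (length(m) < 2L) stop("gene feature without ID attribute in ", path)
      m[[2]]
    }, "")
    start1 <- vapply(fields, function(f) as.integer(f[[4]]), 1L)
    end1   <- vapply(fields, function(f) as.integer(f[[5]]), 1L)
    strand <- vapply(fields, function(f) f[[7]], "")
    df <- data.frame(gene_id = ids,
                     chrom = vapply(fields, `[[`, "", 1L),
                     tss = ifelse(strand == "+", start1 - 1L, end1 - 1L),
                     strand = strand, stringsAsFactors = FALSE)
  }
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop("duplicate gene_id(s): ", paste(dup, collapse = ", "))
  if ("fpkm_wt" %in% names(df) && any(df$fpkm_wt < 0, na.rm = TRUE))
    stop("negative fpkm_wt")
  df
}

#' Write a gene-model table (TSV dialect)
#' @param genes gene data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OrthoFinder Orthogroups.tsv file
#'
#' First column is the orthogroup id, one column per species, cells are
#' comma-space-separated gene lists (empty cell = no member).
#'
#' @param path path to Orthogroups.tsv.
#' @param species character vector of species to extract; all must appear in
#'   the header.
#' @return A named list (one element per orthogroup id) of named lists of
#'   per-species gene-id character vectors.
#' @export
read_orthogroups <- function(path, species) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty orthogroups file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(species, header[-1])
  if (length(miss))
    stop("species absent from the orthogroups header: ",
         paste(miss, collapse = ", "))
  idx <- match(species, header)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  out <- lapply(body, function(f) {
    cells <- vapply(idx, function(i) if (length(f) >= i) f[[i]] else "", "")
    g <- lapply(cells, function(cell) {
      if (!nzchar(cell)) return(character())
      trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    names(g) <- species
    g
  })
  names(out) <- vapply(body, `[[`, "", 1L)
  all_genes <- unlist(out, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup))
    stop("gene(s) assigned to more than one orthogroup: ",
         paste(utils::head(dup, 5), collapse = ", "))
  out
}

#' Read a variant-panel TSV
#'
#' A simplified per-site panel: columns `chrom`, `pos` (0-based),
#' `n_haplotypes`, and either `freqs` (comma-separated allele frequencies
#' summing to 1) or a precomputed `pi` column. Both representations may be
#' mixed across rows; `pi` takes precedence where present.
#'
#' @param path path to the TSV (with header).
#' @return data.frame with `chrom`, `pos`, `n_haplotypes`, `freqs` (list
#'   column, `NULL` where precomputed) and `pi` (`NA` where to be computed).
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer"))
  .stopifnot_cols(df, c("chrom", "pos", "n_haplotypes"), "variant table")
  if (!("freqs" %in% names(df)) && !("pi" %in% names(df)))
    stop("variant table needs a 'freqs' or 'pi' column")
  if (any(df$n_haplotypes < 2L))
    stop("n_haplotypes < 2 at row(s): ", paste(which(df$n_haplotypes < 2L), collapse = ", "))
  freqs <- if ("freqs" %in% names(df)) {
    lapply(df$freqs, function(s) {
      if (is.na(s) || !nzchar(s)) return(NULL)
      as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  } else rep(list(NULL), nrow(df))
  pi <- if ("pi" %in% names(df)) as.numeric(df$pi) else rep(NA_real_, nrow(df))
  need <- is.na(pi)
  bad <- which(need & vapply(freqs, function(p)
    is.null(p) || abs(sum(p) - 1) > 1e-6, TRUE))
  if (length(bad))
    stop("allele frequencies missing or not summing to 1 at row(s): ",
         paste(bad, collapse = ", "))
  data.frame(chrom = df$chrom, pos = df$pos, n_haplotypes = df$n_haplotypes,
             freqs = I(freqs), pi = pi, stringsAsFactors = FALSE)
}
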