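#' Write contigs to FASTA
#'
#' @param contigs contig table with `contig_id` and `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contig_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- contigs$contig_id
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read contig sequences from FASTA
#'
#' @param path FASTA file.
#' @return data frame `contig_id, length, sequence`.
#' @export
read_contig_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(contig_id = names(x), length = Biostrings::width(x),
             sequence = as.character(x), stringsAsFactors = FALSE)
}

# INFO keys of the caller VCF dialect, in column order.
.vcf_info_keys <- c("MQ", "MMLQ", "QD", "PP", "SbPval", "HapScore", "MGOF", "SC")

#' Write a caller variant set as a VCF-dialect file
#'
#' Emits a VCF 4.2 file whose INFO field carries the per-site quality
#' annotations (`MQ, MMLQ, QD, PP, SbPval, HapScore, MGOF, SC`) and whose
#' single sample column carries allelic depths (`FORMAT=AD`, ref first).
#' Unannotated values (the confirming caller emits none) are written as
#' `.`.
#'
#' @param set caller variant data frame (see [generate_caller_sets()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=sprucesnp-%s", as.character(utils::packageVersion("sprucesnp"))),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            .vcf_info_keys, .vcf_info_keys),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           unique(set$caller_id)[1] %||% "SAMPLE")
  ), con)
  if (nrow(set)) {
    fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.10g", x))
    info <- do.call(paste, c(lapply(.vcf_info_keys, function(k) {
      paste0(k, "=", fmt_num(set[[k]]))
    }), sep = ";"))
    ad <- paste(set$ref_reads, set$alt_reads, sep = ",")
    writeLines(paste(set$contig_id, set$pos, ".", set$ref, set$alt, ".",
                     "PASS", info, "AD", ad, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a caller variant set from the VCF dialect
#'
#' Inverse of [write_caller_vcf()].
#'
#' @param path VCF file.
#' @param caller_id caller label to attach (`A` or `B`).
#' @return caller variant data frame.
#' @export
read_caller_vcf <- function(path, caller_id = "A") {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) return(empty_caller_set())
  parts <- strsplit(body, "\t", fixed = TRUE)
  mat <- do.call(rbind, parts)
  info <- strsplit(mat[, 8], ";", fixed = TRUE)
  info_val <- function(k) {
    vapply(info, function(kv) {
      hit <- kv[startsWith(kv, paste0(k, "="))]
      v <- sub("^[^=]+=", "", hit[1])
      if (length(hit) == 0L || v == ".") NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  ad <- strsplit(mat[, 10], ",", fixed = TRUE)
  out <- data.frame(
    caller_id = caller_id, contig_id = mat[, 1], pos = as.integer(mat[, 2]),
    ref = mat[, 4], alt = mat[, 5], stringsAsFactors = FALSE
  )
  for (k in .vcf_info_keys) out[[k]] <- info_val(k)
  out$ref_reads <- vapply(ad, function(v) as.integer(v[1]), integer(1))
  out$alt_reads <- vapply(ad, function(v) paste(v[-1], collapse = ","),
                          character(1))
  out
}

#' Write / read a tab-separated table
#'
#' Plain TSV with header, no quoting, `NA` as `NA`.
#'
#' @param x data frame.
#' @param path file path.
#' @return `write_tsv()` returns `path` invisibly; `read_tsv()` the data
#'   frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a genotype matrix as wide TSV
#'
#' Markers in rows, samples in columns, calls `AA`/`AB`/`BB`/`NC`; the
#' first column holds marker ids.
#'
#' @param calls character matrix with marker rownames.
#' @param path file path.
#' @return `write_genotype_matrix()` returns `path` invisibly;
#'   `read_genotype_matrix()` the character matrix.
#' @export
write_genotype_matrix <- function(calls, path) {
  df <- data.frame(marker_id = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a GenomeStudio-style full data table export
#'
#' Accepts the wide "Full Data Table" text export: a header line followed
#' by one row per marker with a `Name` (or first) column of marker ids, a
#' `GenTrain Score` column if present, and per-sample genotype columns
#' (suffix `.GType` or plain sample names). Genotypes `NC`, `--` and empty
#' cells are normalised to `NC`.
#'
#' @param path export file.
#' @return list with `calls` (character matrix) and `gentrain` (numeric
#'   vector or `NULL`).
#' @export
read_genomestudio_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  name_col <- if ("Name" %in% names(df)) "Name" else names(df)[1]
  gt_col <- grep("GenTrain", names(df), value = TRUE)
  gtype_cols <- grep("\\.GType$", names(df), value = TRUE)
  if (length(gtype_cols) == 0L) {
    gtype_cols <- setdiff(names(df), c(name_col, gt_col))
  }
  m <- as.matrix(df[, gtype_cols, drop = FALSE])
  m[m %in% c("--", "", "NC") | is.na(m)] <- "NC"
  rownames(m) <- df[[name_col]]
  colnames(m) <- sub("\\.GType$", "", gtype_cols)
  list(calls = m,
       gentrain = if (length(gt_col)) as.numeric(df[[gt_col[1]]]) else NULL)
}
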