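#' @name io
#' @title Readers and writers for the pipeline's plain-text formats
#'
#' @description
#' All tables are UTF-8 TSV with a header row and a leading id column.
#' Expression matrices are written genes-as-rows with a `gene_id` column and
#' sample ids as remaining column names. FASTA honours soft-masking
#' (lower-case bases survive the round trip). BED intervals are 0-based,
#' half-open. VCF is v4.2 with 1-based positions. PWMs use JASPAR-style
#' text: a `>id` header line then four `A|C|G|T [counts]` rows.
NULL

#' Write / read a gene x sample matrix as TSV
#'
#' @param mat Numeric matrix with rownames (gene ids) and colnames (samples).
#' @param path File path.
#' @return `read_matrix_tsv()` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Write / read an expression bundle as a directory of TSV files
#'
#' Writes `expression.tsv` (log2 values), `detected.tsv` (0/1),
#' `detection_p.tsv` (if present), `samples.tsv` and `genes.tsv`.
#'
#' @param bundle An [expression_bundle()].
#' @param dir Directory (created if needed).
#' @return `read_expression_bundle()` returns the bundle.
#' @export
write_expression_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "expression_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(bundle$values, file.path(dir, "expression.tsv"))
  write_matrix_tsv(bundle$detected + 0L, file.path(dir, "detected.tsv"))
  if (!is.null(bundle$detection_p)) {
    write_matrix_tsv(bundle$detection_p, file.path(dir, "detection_p.tsv"))
  }
  readr::write_tsv(bundle$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(bundle$genes, file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' @rdname write_expression_bundle
#' @export
read_expression_bundle <- function(dir) {
  values <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  detected <- read_matrix_tsv(file.path(dir, "detected.tsv")) > 0
  pp <- file.path(dir, "detection_p.tsv")
  detection_p <- if (file.exists(pp)) read_matrix_tsv(pp) else NULL
  expression_bundle(
    values,
    samples = readr::read_tsv(file.path(dir, "samples.tsv"),
                              show_col_types = FALSE),
    genes = readr::read_tsv(file.path(dir, "genes.tsv"),
                            show_col_types = FALSE),
    detected = detected, detection_p = detection_p
  )
}

#' Write / read FASTA preserving soft-masking case
#'
#' @param sequences Named character vector.
#' @param path File path.
#' @return `read_fasta()` returns a named character vector with the original
#'   case (lower-case = soft-masked) intact.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(sequences), names = names(sequences),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  s <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(vapply(s, as.character, ""), names(s))
}

#' Write / read BED intervals (0-based, half-open)
#'
#' Columns: chrom, start, end, name, and optionally score and strand (BED6).
#'
#' @param bed Tibble with columns `seq_id`, `start`, `end`, `name`, and
#'   optionally `score`, `strand`.
#' @param path File path.
#' @return `read_bed()` returns the tibble.
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("seq_id", "start", "end", "name", "score", "strand"),
                    names(bed))
  readr::write_tsv(bed[, cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(df) <- c("seq_id", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' Write motif matches as BED6
#'
#' Score column is `round(score_fraction * 1000)`; name is the motif id.
#' @param matches Tibble from [scan_sequence()].
#' @param path File path.
#' @export
write_matches_bed <- function(matches, path) {
  bed <- tibble(seq_id = matches$seq_id, start = matches$start,
                end = matches$end, name = matches$motif_id,
                score = round(matches$score_fraction * 1000),
                strand = matches$strand)
  write_bed(bed, path)
}

#' Write / read JASPAR-style PWM text
#'
#' Format per motif: a `>motif_id` line, then four lines
#' `A  [ n1 n2 ... ]` for A, C, G, T counts.
#'
#' @param pwms List of [pwm()] objects.
#' @param path File path.
#' @param counts_scale Counts written as `round(prob * counts_scale)`.
#' @return `read_pwms_jaspar()` returns a named list of [pwm()] objects.
#' @export
write_pwms_jaspar <- function(pwms, path, counts_scale = 100) {
  lines <- unlist(lapply(pwms, function(p) {
    counts <- round(p$prob * counts_scale)
    c(paste0(">", p$id),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste0(b, "  [ ", paste(counts[b, ], collapse = " "), " ]")
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pwms_jaspar
#' @export
read_pwms_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  stopifnot(length(starts) > 0)
  out <- lapply(starts, function(s) {
    id <- strsplit(sub("^>\\s*", "", lines[s]), "\\s+")[[1]][1]
    rows <- lines[(s + 1):(s + 4)]
    bases <- toupper(sub("^\\s*([ACGTacgt]).*", "\\1", rows))
    counts <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(regmatches(r, gregexpr("-?[0-9.]+", r))[[1]])
    }))
    rownames(counts) <- bases
    pwm(counts[c("A", "C", "G", "T"), , drop = FALSE], id = id,
        source = "file")
  })
  setNames(out, vapply(out, function(p) p$id, ""))
}

#' Write / read a VCF v4.2 file of biallelic SNVs
#'
#' @param variants Tibble with `variant_id`, `seq_id`, `pos` (1-based),
#'   `ref`, `alt` and optionally `risk_allele` (stored in INFO as `RISK=`).
#' @param path File path.
#' @param contig_lengths Optional named vector for `##contig` header lines.
#' @return `read_vcf()` (requires the vcfR package) returns the tibble.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=RISK,Number=1,Type=String,Description="Risk allele (ref or alt)">'
  )
  if (!is.null(contig_lengths)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_lengths), contig_lengths))
  }
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(variants) > 0) {
    info <- if ("risk_allele" %in% names(variants)) {
      paste0("RISK=", variants$risk_allele)
    } else "."
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                    variants$seq_id, variants$pos, variants$variant_id,
                    variants$ref, variants$alt, info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf() requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fx) == 0) {
    return(tibble(variant_id = character(), seq_id = character(),
                  pos = integer(), ref = character(), alt = character(),
                  risk_allele = character()))
  }
  info <- vcfR::extract.info(v, "RISK")
  tibble(variant_id = fx$ID, seq_id = fx$CHROM, pos = as.integer(fx$POS),
         ref = fx$REF, alt = fx$ALT, risk_allele = info)
}

#' Write / read a genotype dosage matrix (variants x individuals) as TSV
#'
#' @param genotypes Integer matrix, rownames = variant ids.
#' @param path File path.
#' @return `read_genotypes_tsv()` returns the matrix.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- tibble::as_tibble(genotypes, rownames = "variant_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read planted ground truth as JSON
#'
#' @param truth A list of planted ground-truth components.
#' @param path File path.
#' @return `read_ground_truth_json()` returns the list (tibbles restored as
#'   data frames).
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
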