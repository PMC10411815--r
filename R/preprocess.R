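#' Aggregate interval signal into fixed-width genomic regions
#'
#' Integrates interval-valued signal (BED-like: chrom, start, end, value)
#' over consecutive fixed-width windows of one chromosome — the "genomic
#' regions" used throughout the pipeline (25,000 nt by default). Region
#' `b` covers nucleotides `[b * bin_size, (b + 1) * bin_size)` in 0-based
#' half-open coordinates. An interval spanning a region boundary is split
#' proportionally to its overlap length with each region.
#'
#' @param intervals a data.frame with columns `chrom`, `start`, `end`,
#'   `value` (0-based half-open, single chromosome), or a named list of
#'   such data.frames, one per subject.
#' @param bin_size region width in nucleotides (default 25000).
#' @param mode `"sum"` (read-count-like signal: each interval's value is
#'   apportioned to regions by overlap fraction and summed) or `"mean"`
#'   (percentage-like signal: length-weighted mean of interval values
#'   overlapping the region). Regions with no overlapping interval get 0.
#' @param chrom_length optional chromosome length; fixes the number of
#'   regions to `ceiling(chrom_length / bin_size)`. Defaults to the
#'   largest interval end seen, so trailing empty regions are dropped.
#' @param layer omics layer label for the returned [omics_matrix()].
#'
#' @return When `intervals` is a list: an [omics_matrix()] with one row per
#'   region and one column per subject. When it is a single data.frame: a
#'   one-column matrix of binned values (regions in rows).
#' @export
#' @examples
#' iv <- data.frame(chrom = "chr1", start = 100, end = 200, value = 4)
#' bin_signal(iv, bin_size = 25000)[1, ]
bin_signal <- function(intervals, bin_size = 25000L, mode = c("sum", "mean"),
                       chrom_length = NULL, layer = "expression") {
  mode <- match.arg(mode)
  stopifnot(length(bin_size) == 1L, bin_size >= 1)
  bin_size <- as.numeric(bin_size)
  if (is.data.frame(intervals)) {
    return(bin_one_subject(intervals, bin_size, mode, chrom_length))
  }
  stopifnot(is.list(intervals), length(intervals) >= 1L)
  chrom <- unique(unlist(lapply(intervals, function(d)
    if (nrow(d)) as.character(d$chrom) else character())))
  if (length(chrom) > 1L) stop("mixed chromosomes in one bin_signal call")
  if (is.null(chrom_length)) {
    ends <- unlist(lapply(intervals, function(d) d$end))
    chrom_length <- if (length(ends)) max(ends) else 0
  }
  cols <- lapply(intervals, bin_one_subject, bin_size = bin_size,
                 mode = mode, chrom_length = chrom_length)
  values <- do.call(cbind, cols)
  n_bins <- nrow(values)
  starts <- (seq_len(n_bins) - 1) * bin_size
  ids <- sprintf("%s:%d-%d", if (length(chrom)) chrom else "chr?",
                 as.integer(starts),
                 as.integer(pmin(starts + bin_size, chrom_length)))
  subject_ids <- names(intervals) %||% paste0("S", seq_along(intervals))
  omics_matrix(values, layer = layer,
               chrom = if (length(chrom)) chrom else NA_character_,
               feature_ids = ids, subject_ids = subject_ids)
}

bin_one_subject <- function(d, bin_size, mode, chrom_length = NULL) {
  need <- c("start", "end", "value")
  if (!all(need %in% names(d)))
    stop("intervals need columns chrom, start, end, value")
  if (nrow(d) && length(unique(as.character(d$chrom))) > 1L)
    stop("mixed chromosomes in one bin_signal call")
  start <- as.numeric(d$start); end <- as.numeric(d$end)
  value <- as.numeric(d$value)
  if (any(start < 0)) stop("negative coordinates are not allowed")
  if (any(start >= end)) stop("intervals must satisfy start < end")
  if (is.null(chrom_length)) chrom_length <- if (nrow(d)) max(end) else 0
  n_bins <- as.integer(ceiling(chrom_length / bin_size))
  out <- numeric(n_bins)
  if (n_bins == 0L || nrow(d) == 0L)
    return(matrix(out, ncol = 1L))
  if (any(end > n_bins * bin_size))
    stop("interval end exceeds the declared chromosome length")
  ## regular tiling: bin membership is integer division; expand each
  ## interval over the bins it touches and clip to bin boundaries
  b0 <- floor(start / bin_size)
  b1 <- floor((end - 1) / bin_size)
  nspan <- as.integer(b1 - b0 + 1)
  idx <- rep.int(seq_along(start), nspan)
  bin <- unlist(lapply(seq_along(start), function(i) b0[i]:b1[i]))
  ov <- pmin(end[idx], (bin + 1) * bin_size) - pmax(start[idx], bin * bin_size)
  if (mode == "sum") {
    contrib <- value[idx] * ov / (end[idx] - start[idx])
    acc <- rowsum(contrib, bin)
    out[as.integer(rownames(acc)) + 1L] <- acc[, 1L]
  } else {
    wsum <- rowsum(value[idx] * ov, bin)
    lsum <- rowsum(ov, bin)
    out[as.integer(rownames(wsum)) + 1L] <- wsum[, 1L] / lsum[, 1L]
  }
  matrix(out, ncol = 1L)
}

#' Encode diploid genotype calls as 012 dosage
#'
#' Converts per-variant, per-subject genotype calls into the count of
#' non-reference alleles (0, 1 or 2). Calls may be VCF-style strings
#' (`"0/0"`, `"0|1"`, `"./."`, optionally with trailing FORMAT fields
#' after a colon) or a numeric matrix already in 012 form with `NA` for
#' missing. Multiallelic calls count any non-reference allele.
#'
#' @param calls character or numeric matrix, variants in rows, subjects in
#'   columns.
#' @param missing how to handle missing calls: `"mean"` (default) imputes
#'   the variant's mean dosage over non-missing subjects; `"drop"` removes
#'   the variant. Variants missing in every subject are always dropped,
#'   with a warning.
#' @param chrom chromosome label for the returned [omics_matrix()].
#'
#' @return An [omics_matrix()] with `layer = "variant"`; values lie in
#'   \[0, 2\] and are integers wherever no imputation occurred.
#' @export
#' @examples
#' g <- matrix(c("0/0", "0/1", "1/1"), 1, 3)
#' encode_genotypes(g)$values
encode_genotypes <- function(calls, missing = c("mean", "drop"),
                             chrom = "chr?") {
  missing <- match.arg(missing)
  calls <- as.matrix(calls)
  if (is.numeric(calls)) {
    ok <- is.na(calls) | (calls >= 0 & calls <= 2)
    if (!all(ok)) stop("numeric dosages must lie in [0, 2] or be NA")
    dose <- calls
  } else {
    gt <- sub(":.*$", "", as.character(calls))
    sep_ok <- !is.na(gt) & grepl("^[^/|]+[/|][^/|]+$", gt)
    miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
    if (any(!sep_ok & !miss))
      stop("unsupported genotype (ploidy != 2): ",
           paste(utils::head(unique(gt[!sep_ok & !miss]), 3), collapse = ", "))
    gt[miss] <- "./."
    a1 <- sub("^([^/|]+)[/|].*$", "\\1", gt)
    a2 <- sub("^[^/|]+[/|]([^/|]+)$", "\\1", gt)
    allele_dose <- function(a) {
      d <- rep(NA_real_, length(a))
      d[a == "."] <- NA_real_
      num <- suppressWarnings(as.numeric(a))
      bad <- a != "." & is.na(num)
      if (any(bad)) stop("unparseable allele in genotype call: ",
                         paste(utils::head(unique(a[bad]), 3), collapse = ", "))
      d[!is.na(num)] <- as.numeric(num[!is.na(num)] > 0)
      d
    }
    d1 <- allele_dose(a1); d2 <- allele_dose(a2)
    d1[miss] <- NA_real_; d2[miss] <- NA_real_
    dose <- matrix(d1 + d2, nrow(calls), ncol(calls))
    dimnames(dose) <- dimnames(calls)
  }
  n_miss <- rowSums(is.na(dose))
  all_missing <- n_miss == ncol(dose)
  if (any(all_missing)) {
    warning(sum(all_missing),
            " variant(s) missing in all subjects were dropped")
    dose <- dose[!all_missing, , drop = FALSE]
    n_miss <- n_miss[!all_missing]
  }
  if (nrow(dose) == 0L) stop("no variants left after dropping all-missing rows")
  if (any(n_miss > 0L)) {
    if (missing == "drop") {
      dose <- dose[n_miss == 0L, , drop = FALSE]
      if (nrow(dose) == 0L)
        stop("no variants left after dropping rows with missing calls")
    } else {
      means <- rowMeans(dose, na.rm = TRUE)
      na_idx <- which(is.na(dose), arr.ind = TRUE)
      dose[na_idx] <- means[na_idx[, 1L]]
    }
  }
  omics_matrix(dose, layer = "variant", chrom = chrom)
}

#' Read genotypes from a VCF file as 012 dosage matrices
#'
#' Thin wrapper over \pkg{vcfR} that extracts the GT field and encodes it
#' with [encode_genotypes()], splitting by chromosome.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @inheritParams encode_genotypes
#' @return A named list of [omics_matrix()] objects, one per chromosome
#'   present in the file.
#' @export
read_vcf_genotypes <- function(path, missing = c("mean", "drop")) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_genotypes requires the vcfR package")
  missing <- match.arg(missing)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  ids <- rownames(gt) %||% sprintf("%s:%d", chrom, pos)
  rownames(gt) <- ids
  out <- lapply(split(seq_len(nrow(gt)), chrom), function(i)
    encode_genotypes(gt[i, , drop = FALSE], missing = missing,
                     chrom = chrom[i[1L]]))
  out[order(names(out))]
}

#' Read a plain 012 dosage table
#'
#' @param path TSV with variants in rows (first column = variant ID) and
#'   subjects in columns; entries 0/1/2 or NA.
#' @inheritParams encode_genotypes
#' @return An [omics_matrix()] with `layer = "variant"`.
#' @export
read_012_tsv <- function(path, missing = c("mean", "drop"), chrom = "chr?") {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- as.character(d[[1L]])
  encode_genotypes(m, missing = missing, chrom = chrom)
}

#' Read per-subject BED signal files and bin them into genomic regions
#'
#' @param files named character vector of BED file paths
#'   (chrom, start, end, value; no header), names = subject IDs.
#' @inheritParams bin_signal
#' @return An [omics_matrix()] of binned signal.
#' @export
read_bed_signal <- function(files, bin_size = 25000L, mode = c("sum", "mean"),
                            chrom_length = NULL, layer = "expression") {
  mode <- match.arg(mode)
  stopifnot(length(files) >= 1L)
  if (is.null(names(files)))
    names(files) <- sub("\\.bed$", "", basename(files))
  ivs <- lapply(files, function(f) {
    d <- utils::read.delim(f, header = FALSE,
                           col.names = c("chrom", "start", "end", "value"))
    d
  })
  bin_signal(ivs, bin_size = bin_size, mode = mode,
             chrom_length = chrom_length, layer = layer)
}

#' Write an omics matrix as a wide TSV
#'
#' One row per feature: `feature_id`, then one column per subject.
#' @param om an [omics_matrix()].
#' @param path output path.
#' @export
write_omics_tsv <- function(om, path) {
  d <- data.frame(feature_id = om$feature_ids, om$values,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
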