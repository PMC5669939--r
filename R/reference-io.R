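#' Read a mature miRNA FASTA file
#'
#' Reads miRBase-style mature sequences. Sequences are uppercased and U is
#' converted to T so that references and reads share one DNA alphabet. The
#' record id is the first whitespace-delimited header token; the remainder of
#' the header is kept as a free-text description.
#'
#' @param path path to a FASTA file (multi-line records allowed).
#' @return A named [Biostrings::DNAStringSet]; `mcols(x)$description` holds
#'   the header remainder.
#' @export
readMatureFasta <- function(path) readFastaDna(path, what = "mature")

#' Read a hairpin (pre-miRNA) FASTA file
#'
#' @inheritParams readMatureFasta
#' @return A named [Biostrings::DNAStringSet] with descriptions in `mcols`.
#' @export
readHairpinFasta <- function(path) readFastaDna(path, what = "hairpin")

readFastaDna <- function(path, what = "sequence") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("cannot read FASTA ", path, ": ",
                                         conditionMessage(e)))
  if (length(x) == 0L) stop("no records in ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate ", what, " id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGTU]", seqs)
  if (any(bad))
    stop("non-ACGTU character in ", what, " record ", ids[bad][1L])
  seqs <- chartr("U", "T", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Link mature miRNAs to their hairpins
#'
#' Locates each mature as an exact substring of its hairpin and records the
#' first (lowest-start) occurrence as 0-based half-open coordinates. Matures
#' that occur more than once on their hairpin are resolved to the lowest start
#' and reported in the `multi_hit` attribute (and via a warning).
#'
#' @param matures named [Biostrings::DNAStringSet] of mature sequences.
#' @param hairpins named [Biostrings::DNAStringSet] of hairpin sequences.
#' @param mapping named character vector, `mature_id -> hairpin_id`. By
#'   default each mature is searched on the hairpin with the same index
#'   position, which suits simulated references; real references should pass
#'   an explicit mapping.
#' @return A [MirnaReference-class]; `metadata(...)$multi_hit` lists mature
#'   ids with multiple occurrences.
#' @export
linkMatureToHairpin <- function(matures, hairpins,
                                mapping = setNames(names(hairpins),
                                                   names(matures))) {
  if (is.null(names(matures)) || is.null(names(hairpins)))
    stop("matures and hairpins must be named")
  if (!all(names(matures) %in% names(mapping)))
    stop("mapping missing mature id: ",
         setdiff(names(matures), names(mapping))[1L])
  hid <- unname(mapping[names(matures)])
  if (!all(hid %in% names(hairpins)))
    stop("hairpin not found: ", setdiff(hid, names(hairpins))[1L])

  mseq <- as.character(matures)
  hseq <- as.character(hairpins)[hid]
  start <- integer(length(matures))
  multi <- character(0)
  for (i in seq_along(mseq)) {
    hits <- gregexpr(mseq[i], hseq[i], fixed = TRUE)[[1L]]
    if (hits[1L] == -1L)
      stop("mature ", names(matures)[i], " not found in hairpin ", hid[i])
    if (length(hits) > 1L) multi <- c(multi, names(matures)[i])
    start[i] <- hits[1L] - 1L
  }
  if (length(multi) > 0)
    warning("mature occurs multiple times on its hairpin (first occurrence ",
            "used): ", paste(multi, collapse = ", "))
  map <- S4Vectors::DataFrame(mature_id = names(matures), hairpin_id = hid,
                              start = start,
                              end = start + unname(nchar(mseq)))
  ref <- new("MirnaReference", matures = matures, hairpins = hairpins,
             map = map)
  S4Vectors::metadata(ref@map)$multi_hit <- multi
  ref
}

#' Read / write a feature-by-sample count table
#'
#' TSV layout: header row with a `feature_id` corner cell followed by sample
#' ids; one row per feature. Counts must be non-negative integers (fractional
#' values are rejected, not rounded). `writeCountsTsv` followed by
#' `readCountsTsv` is the identity.
#'
#' @param path TSV path.
#' @return `readCountsTsv`: an integer matrix with feature rownames and sample
#'   colnames.
#' @export
readCountsTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L) stop("empty count table: ", path)
  if (length(unique(nf)) != 1L) stop("ragged rows in count table: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("count table needs a feature column and >= 1 sample")
  samples <- colnames(df)[-1L]
  corner <- colnames(df)[1L]
  if (!is.na(suppressWarnings(as.numeric(corner))) ||
      any(!is.na(suppressWarnings(as.numeric(samples)))))
    stop("count table appears to be missing its header row: ", path)
  features <- df[[1L]]
  if (anyDuplicated(features)) stop("duplicate feature id: ",
                                    features[duplicated(features)][1L])
  if (anyDuplicated(samples)) stop("duplicate sample id: ",
                                   samples[duplicated(samples)][1L])
  vals <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(features, samples))
  if (anyNA(vals)) stop("non-numeric count in table: ", path)
  if (any(vals < 0)) stop("negative count in table: ", path)
  if (any(vals != round(vals))) stop("fractional count in table: ", path)
  storage.mode(vals) <- "integer"
  vals
}

#' @rdname readCountsTsv
#' @param counts integer matrix (features x samples) with dimnames.
#' @export
writeCountsTsv <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with columns exactly `sample_id`, `group_id`, `replicate`
#' (replicate an integer >= 1). `(group_id, replicate)` pairs must be unique.
#'
#' @param path TSV path.
#' @return data.frame with the three columns.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "")
  need <- c("sample_id", "group_id", "replicate")
  if (!identical(colnames(df), need))
    stop("sample sheet columns must be exactly: ",
         paste(need, collapse = ", "))
  validateSampleSheet(df)
}

validateSampleSheet <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet")
  rep <- suppressWarnings(as.numeric(df$replicate))
  if (anyNA(rep) || any(rep < 1) || any(rep != round(rep)))
    stop("replicate must be an integer >= 1")
  df$replicate <- as.integer(rep)
  if (anyDuplicated(df[, c("group_id", "replicate")]))
    stop("(group_id, replicate) pairs must be unique")
  df$sample_id <- as.character(df$sample_id)
  df$group_id <- as.character(df$group_id)
  df
}

#' @rdname readSampleSheet
#' @param sheet data.frame with columns sample_id, group_id, replicate.
#' @export
writeSampleSheet <- function(sheet, path) {
  write.table(sheet[, c("sample_id", "group_id", "replicate")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a snoRNA annotation table
#'
#' TSV with columns `id`, `box_class`, `length` and optionally `host_gene`.
#' Box-class labels are normalized case-insensitively (punctuation ignored)
#' to `CD` (C/D box), `HACA` (H/ACA box) or `SCARNA` (small Cajal
#' body-specific); anything else is an error.
#'
#' @param path TSV path.
#' @return data.frame with columns id, box_class, length, host_gene (NA when
#'   absent).
#' @export
readSnoAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "")
  need <- c("id", "box_class", "length")
  if (!all(need %in% colnames(df)))
    stop("snoRNA annotation needs columns: ", paste(need, collapse = ", "))
  norm <- gsub("[^A-Z]", "", toupper(as.character(df$box_class)))
  bad <- !(norm %in% SNO_CLASSES)
  if (any(bad))
    stop("unknown snoRNA box class '", df$box_class[bad][1L], "' for id ",
         df$id[bad][1L])
  len <- suppressWarnings(as.numeric(df$length))
  if (anyNA(len) || any(len <= 0)) stop("snoRNA length must be > 0")
  if (anyDuplicated(df$id)) stop("duplicate snoRNA id")
  data.frame(id = as.character(df$id), box_class = norm,
             length = as.integer(len),
             host_gene = if ("host_gene" %in% colnames(df))
               as.character(df$host_gene) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Combine counts and a sample sheet into a SummarizedExperiment
#'
#' @param counts integer matrix (features x samples).
#' @param sheet sample sheet data.frame covering every sample column.
#' @return [SummarizedExperiment::SummarizedExperiment] with a `counts` assay
#'   and `group_id`/`replicate` in `colData`.
#' @export
cargoExperiment <- function(counts, sheet) {
  sheet <- validateSampleSheet(sheet)
  if (!all(colnames(counts) %in% sheet$sample_id))
    stop("sample sheet missing sample: ",
         setdiff(colnames(counts), sheet$sample_id)[1L])
  cd <- sheet[match(colnames(counts), sheet$sample_id), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group_id = cd$group_id,
                                   replicate = cd$replicate,
                                   row.names = cd$sample_id))
}
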