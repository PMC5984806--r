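# Minimal reader for Illumina IDAT intensity files (format version >= 3).
# Only the fields needed for QC are decoded: the number of bead types,
# their addresses ("IlluminaID") and the mean intensity per bead type.

IDAT_FIELD_NSNPS <- 1000L
IDAT_FIELD_ID    <- 102L
IDAT_FIELD_MEAN  <- 104L

#' Read one IDAT file
#'
#' Decodes bead addresses and mean intensities from a single-channel
#' Illumina IDAT file.
#'
#' @param path path to an `.idat` file.
#' @return list with integer vectors `ids` (bead addresses) and `means`
#'   (mean intensity per bead type).
#' @export
read_idat <- function(path) {
  if (!file.exists(path)) stop("IDAT file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "IDAT"))
    stop("not an IDAT file (bad magic bytes): ", path, call. = FALSE)
  version <- readBin(con, "integer", n = 1L, size = 8L, endian = "little")
  if (length(version) == 0L || version < 3L)
    stop("unsupported IDAT version (need >= 3): ", path, call. = FALSE)
  n_fields <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(n_fields) == 0L || n_fields < 1L)
    stop("truncated IDAT file: ", path, call. = FALSE)
  codes <- integer(n_fields); offsets <- numeric(n_fields)
  for (i in seq_len(n_fields)) {
    code <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                    endian = "little")
    # offsets are int64 on disk; assemble from two little-endian int32 words
    lo <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    hi <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(code) == 0L || length(lo) == 0L || length(hi) == 0L)
      stop("truncated IDAT file: ", path, call. = FALSE)
    codes[i] <- code
    if (lo < 0) lo <- lo + 2^32
    offsets[i] <- lo + hi * 2^32
  }

  field_offset <- function(code) {
    k <- which(codes == code)
    if (length(k) == 0L) NA_real_ else offsets[k[1L]]
  }
  off <- field_offset(IDAT_FIELD_NSNPS)
  if (is.na(off)) stop("IDAT file lacks bead-count field: ", path, call. = FALSE)
  seek(con, off)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(n) == 0L) stop("truncated IDAT file: ", path, call. = FALSE)
  if (n == 0L) stop("IDAT file contains zero probe records: ", path, call. = FALSE)

  off <- field_offset(IDAT_FIELD_ID)
  if (is.na(off)) stop("IDAT file lacks IlluminaID field: ", path, call. = FALSE)
  seek(con, off)
  ids <- readBin(con, "integer", n = n, size = 4L, endian = "little")

  off <- field_offset(IDAT_FIELD_MEAN)
  if (is.na(off)) stop("IDAT file lacks Mean field: ", path, call. = FALSE)
  seek(con, off)
  means <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                   endian = "little")
  if (length(ids) < n || length(means) < n)
    stop("truncated IDAT file: ", path, call. = FALSE)
  list(ids = ids, means = as.numeric(means))
}

#' Read a green/red IDAT pair into a single-sample dataset
#'
#' Bead addresses are mapped to probes through the manifest columns
#' `address_a` and `address_b`: type II probes read M from the green and
#' U from the red channel at `address_a`; type I probes read U at
#' `address_a` and M at `address_b`, both in their design channel.
#' Control probes read both channels at `address_a`. Addresses present in
#' the IDAT but absent from the manifest are dropped with a warning.
#'
#' @param grn_path,red_path paths to the green/red channel `.idat` files.
#' @param manifest_path path to a manifest TSV carrying `address_a`
#'   (and `address_b` for type I probes).
#' @param sample_id sample identifier for the decoded sample.
#' @return A single-sample `MethylationDataset`.
#' @export
read_idat_pair <- function(grn_path, red_path, manifest_path,
                           sample_id = "sample1") {
  manifest <- read_manifest(manifest_path)
  if (!all(c("address_a", "address_b") %in% names(manifest)))
    stop("manifest must provide address_a/address_b for IDAT decoding",
         call. = FALSE)
  grn <- read_idat(grn_path)
  red <- read_idat(red_path)

  known <- c(manifest$address_a, manifest$address_b)
  n_unknown <- sum(!unique(c(grn$ids, red$ids)) %in% known)
  if (n_unknown > 0L)
    warning(n_unknown, " bead address(es) not in manifest were dropped")

  lookup <- function(chan, addr) {
    out <- chan$means[match(addr, chan$ids)]
    out
  }
  is_ctl <- manifest$probe_class == "control"
  probes <- manifest[!is_ctl, , drop = FALSE]
  U <- M <- rep(NA_real_, nrow(probes))
  t2 <- probes$channel_design == "typeII"
  M[t2] <- lookup(grn, probes$address_a[t2])
  U[t2] <- lookup(red, probes$address_a[t2])
  t1g <- probes$channel_design == "typeI_green"
  U[t1g] <- lookup(grn, probes$address_a[t1g])
  M[t1g] <- lookup(grn, probes$address_b[t1g])
  t1r <- probes$channel_design == "typeI_red"
  U[t1r] <- lookup(red, probes$address_a[t1r])
  M[t1r] <- lookup(red, probes$address_b[t1r])

  ctl <- manifest[is_ctl, , drop = FALSE]
  controls_grn <- matrix(lookup(grn, ctl$address_a), ncol = 1,
                         dimnames = list(ctl$probe_id, sample_id))
  controls_red <- matrix(lookup(red, ctl$address_a), ncol = 1,
                         dimnames = list(ctl$probe_id, sample_id))

  Um <- matrix(U, ncol = 1, dimnames = list(probes$probe_id, sample_id))
  Mm <- matrix(M, ncol = 1, dimnames = list(probes$probe_id, sample_id))
  samples <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  methylation_dataset(Um, Mm, controls_grn, controls_red, samples, manifest)
}
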