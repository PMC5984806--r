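# Shared fixtures, all built in code.

# minimal manifest: 2 autosomal cpg, 1 X, 1 Y, 2 snp, negative controls
tiny_manifest <- function(n_neg = 4L) {
  data.frame(
    probe_id = c("cg000001", "cg000002", "cg000003", "cg000004",
                 "rs0001", "rs0002",
                 sprintf("ctl_neg_%02d", seq_len(n_neg))),
    chromosome = c("1", "2", "X", "Y", "3", "7", rep(NA_character_, n_neg)),
    probe_class = c(rep("cpg", 4L), rep("snp", 2L), rep("control", n_neg)),
    control_category = c(rep(NA_character_, 6L), rep("negative", n_neg)),
    channel_design = c("typeII", "typeI_green", "typeII", "typeI_red",
                       "typeII", "typeII", rep("typeII", n_neg)),
    stringsAsFactors = FALSE
  )
}

# dataset with hand-set intensities over the tiny manifest
tiny_dataset <- function(U = NULL, M = NULL, n_samples = 2L, neg_level = 100) {
  mf <- tiny_manifest()
  probes <- mf$probe_id[mf$probe_class != "control"]
  samples <- sprintf("s%d", seq_len(n_samples))
  if (is.null(U)) U <- matrix(1000, length(probes), n_samples)
  if (is.null(M)) M <- matrix(1000, length(probes), n_samples)
  dimnames(U) <- dimnames(M) <- list(probes, samples)
  neg <- mf$probe_id[mf$probe_class == "control"]
  cg <- matrix(neg_level * (1 + 0.01 * seq_along(neg)), length(neg), n_samples,
               dimnames = list(neg, samples))
  cr <- matrix(neg_level * (1 + 0.02 * seq_along(neg)), length(neg), n_samples,
               dimnames = list(neg, samples))
  methylation_dataset(U, M, cg, cr,
                      data.frame(sample_id = samples), mf)
}

# write a long-format TSV trio for read_dataset
write_tiny_tsvs <- function(dataset, dir = tempfile("ds")) {
  dir.create(dir, showWarnings = FALSE)
  write_dataset(dataset, dir)
}

# minimal valid version-3 IDAT writer (fields: bead count, IlluminaID, Mean)
write_synthetic_idat <- function(path, ids, means) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("IDAT", con, nchars = 4L, eos = NULL)
  writeBin(c(3L, 0L), con, size = 4L, endian = "little")       # int64 version
  n_fields <- 3L
  writeBin(n_fields, con, size = 4L, endian = "little")
  header_len <- 4L + 8L + 4L + n_fields * 10L
  n <- length(ids)
  off_n <- header_len
  off_id <- off_n + 4L
  off_mean <- off_id + 4L * n
  field <- function(code, offset) {
    writeBin(code, con, size = 2L, endian = "little")
    writeBin(c(as.integer(offset), 0L), con, size = 4L, endian = "little")
  }
  field(1000L, off_n)
  field(102L, off_id)
  field(104L, off_mean)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  writeBin(as.integer(ids), con, size = 4L, endian = "little")
  writeBin(as.integer(means), con, size = 2L, endian = "little")
  invisible(path)
}

# genotype posteriors array from hard calls (sample x snp matrix of 1..3),
# with optional uniform outlier mass
hard_posteriors <- function(calls, outlier = 0) {
  n <- nrow(calls); j <- ncol(calls)
  posts <- array(0, c(n, j, 4L),
                 dimnames = list(rownames(calls), colnames(calls),
                                 c("AA", "AB", "BB", "outlier")))
  for (k in 1:3) posts[, , k] <- (calls == k) * (1 - outlier)
  posts[, , 4L] <- outlier
  posts
}
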