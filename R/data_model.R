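# Core data types: probe manifest and paired-intensity dataset.

CHROMOSOMES <- c(as.character(1:22), "X", "Y")
PROBE_CLASSES <- c("cpg", "snp", "control")
CONTROL_CATEGORIES <- c(
  "staining", "extension", "hybridization", "target_removal",
  "bisulfite_conversion_I", "bisulfite_conversion_II",
  "specificity_I", "specificity_II", "non_polymorphic",
  "restoration", "negative"
)
CHANNEL_DESIGNS <- c("typeI_green", "typeI_red", "typeII")

#' Construct and validate a probe manifest
#'
#' The manifest drives all probe-subset selection: which probes are
#' autosomal CpGs, which target the X or Y chromosome, which query SNPs
#' ("rs" probes) and which are dedicated control probes (and of which
#' control category). Optional integer columns `address_a`/`address_b`
#' carry bead addresses used when decoding raw IDAT files.
#'
#' @param x data.frame with columns `probe_id`, `chromosome`,
#'   `probe_class`, `control_category`, `channel_design` (and optionally
#'   `address_a`, `address_b`).
#' @return A validated `Manifest` (a data.frame).
#' @export
as_manifest <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("probe_id", "chromosome", "probe_class", "channel_design")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L)
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"control_category" %in% names(x)) x$control_category <- NA_character_
  x$probe_id <- as.character(x$probe_id)
  x$chromosome <- as.character(x$chromosome)
  x$control_category[!is.na(x$control_category) & x$control_category == ""] <- NA_character_

  if (anyDuplicated(x$probe_id))
    stop("duplicate probe_id in manifest: ",
         paste(unique(x$probe_id[duplicated(x$probe_id)])[1:3], collapse = ", "),
         call. = FALSE)
  bad <- !x$probe_class %in% PROBE_CLASSES
  if (any(bad))
    stop("unknown probe_class: ", paste(unique(x$probe_class[bad]), collapse = ", "),
         call. = FALSE)
  bad <- !x$channel_design %in% CHANNEL_DESIGNS
  if (any(bad))
    stop("unknown channel_design: ", paste(unique(x$channel_design[bad]), collapse = ", "),
         call. = FALSE)
  is_ctl <- x$probe_class == "control"
  if (any(is_ctl & is.na(x$control_category)))
    stop("control probes must carry a control_category", call. = FALSE)
  if (any(!is_ctl & !is.na(x$control_category)))
    stop("control_category must be absent for non-control probes", call. = FALSE)
  bad <- is_ctl & !x$control_category %in% CONTROL_CATEGORIES
  if (any(bad))
    stop("unknown control_category: ",
         paste(unique(x$control_category[bad]), collapse = ", "), call. = FALSE)
  bad <- !is_ctl & !x$chromosome %in% CHROMOSOMES
  if (any(bad))
    stop("chromosome must be one of 1..22, X, Y for cpg/snp probes", call. = FALSE)
  is_snp <- x$probe_class == "snp"
  if (any(is_snp & !startsWith(x$probe_id, "rs")))
    stop("snp-class probe identifiers must start with \"rs\"", call. = FALSE)

  class(x) <- c("Manifest", "data.frame")
  x
}

#' Select probe identifiers from a manifest
#'
#' Probe classes partition the manifest: every probe matches exactly one
#' of `cpg`/`snp`/`control`, and CpG probes split further by chromosome.
#'
#' @param manifest a `Manifest`.
#' @param subset one of `"autosomal"`, `"chrX"`, `"chrY"`, `"snp"`,
#'   `"control"`.
#' @param control_category optional control category filter (only with
#'   `subset = "control"`).
#' @return character vector of probe ids.
#' @export
probe_subset <- function(manifest,
                         subset = c("autosomal", "chrX", "chrY", "snp", "control"),
                         control_category = NULL) {
  subset <- match.arg(subset)
  keep <- switch(subset,
    autosomal = manifest$probe_class == "cpg" & manifest$chromosome %in% as.character(1:22),
    chrX      = manifest$probe_class == "cpg" & manifest$chromosome == "X",
    chrY      = manifest$probe_class == "cpg" & manifest$chromosome == "Y",
    snp       = manifest$probe_class == "snp",
    control   = manifest$probe_class == "control"
  )
  if (!is.null(control_category)) {
    if (subset != "control")
      stop("control_category filter only applies to subset = \"control\"", call. = FALSE)
    keep <- keep & manifest$control_category %in% control_category
  }
  manifest$probe_id[keep]
}

#' Construct and validate a methylation dataset
#'
#' Bundles the unmethylated/methylated intensity matrices (probe x
#' sample), the control-probe intensities per color channel, the probe
#' manifest and per-sample metadata. Intensities are non-negative;
#' missing measurements are `NA`, never zero, so that downstream
#' averages can skip them.
#'
#' @param U,M numeric matrices (probe x sample) with rownames = probe ids
#'   and colnames = sample ids; same dimnames for both.
#' @param controls_grn,controls_red numeric matrices (control probe x
#'   sample) of green/red channel control intensities.
#' @param samples data.frame with columns `sample_id`, `donor_id`,
#'   `recorded_sex` (one of `"male"`, `"female"`, `"unknown"`).
#' @param manifest a `Manifest` covering every probe row.
#' @return A `MethylationDataset`.
#' @export
methylation_dataset <- function(U, M, controls_grn, controls_red, samples, manifest) {
  manifest <- as_manifest(manifest)
  U <- as.matrix(U); M <- as.matrix(M)
  if (!identical(dim(U), dim(M)) || !identical(dimnames(U), dimnames(M)))
    stop("U and M must share probe and sample indices", call. = FALSE)
  if (is.null(rownames(U)) || is.null(colnames(U)))
    stop("U/M need probe rownames and sample colnames", call. = FALSE)
  for (nm in c("U", "M", "controls_grn", "controls_red")) {
    m <- get(nm)
    if (any(m < 0, na.rm = TRUE))
      stop("negative intensities in ", nm, call. = FALSE)
  }
  unknown <- setdiff(c(rownames(U), rownames(controls_grn), rownames(controls_red)),
                     manifest$probe_id)
  if (length(unknown) > 0L)
    stop("probe(s) absent from manifest: ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples))
    stop("samples metadata needs a sample_id column", call. = FALSE)
  if (!"donor_id" %in% names(samples)) samples$donor_id <- samples$sample_id
  if (!"recorded_sex" %in% names(samples)) samples$recorded_sex <- "unknown"
  samples$recorded_sex[is.na(samples$recorded_sex)] <- "unknown"
  if (!all(samples$recorded_sex %in% c("male", "female", "unknown")))
    stop("recorded_sex must be male/female/unknown", call. = FALSE)
  if (!identical(sort(samples$sample_id), sort(colnames(U))))
    stop("samples metadata does not match intensity matrix columns", call. = FALSE)
  samples <- samples[match(colnames(U), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  structure(
    list(U = U, M = M,
         controls_grn = controls_grn, controls_red = controls_red,
         samples = samples, manifest = manifest),
    class = "MethylationDataset"
  )
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat("MethylationDataset:", nrow(x$U), "probes x", ncol(x$U), "samples\n")
  cat("  control probes:", nrow(x$controls_grn), "(grn) /",
      nrow(x$controls_red), "(red)\n")
  tab <- table(x$manifest$probe_class)
  cat("  manifest:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.MethylationDataset <- function(x) dim(x$U)

# ---- TSV dialect -----------------------------------------------------------

read_tsv_strict <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          quote = "", data.table = FALSE)
  for (col in intersect(c("probe_id", "sample_id"), names(dt)))
    dt[[col]] <- as.character(dt[[col]])
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0L)
    stop("malformed ", what, " header: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dt
}

long_to_matrix <- function(df, value_col) {
  probes <- unique(df$probe_id)
  samples <- unique(df$sample_id)
  m <- matrix(NA_real_, length(probes), length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(df$probe_id, probes), match(df$sample_id, samples))] <-
    as.numeric(df[[value_col]])
  m
}

#' Read a probe manifest from TSV
#'
#' @param path TSV with the `Manifest` columns; UTF-8, no quoting,
#'   missing values as empty fields.
#' @return A `Manifest`.
#' @export
read_manifest <- function(path) {
  df <- read_tsv_strict(path, c("probe_id", "chromosome", "probe_class",
                                "control_category", "channel_design"),
                        "manifest")
  as_manifest(df)
}

#' Read a methylation dataset from the TSV interchange dialect
#'
#' The intensity file is long-format with header
#' `probe_id  sample_id  U  M`; the optional controls file has header
#' `probe_id  sample_id  grn  red`; the optional sample-metadata file has
#' `sample_id` plus optional `donor_id` and `recorded_sex`. Probes absent
#' from the manifest are rejected.
#'
#' @param intensity_path path to the intensity TSV.
#' @param manifest_path path to the manifest TSV.
#' @param controls_path optional path to the control-intensity TSV.
#' @param samples_path optional path to the sample metadata TSV.
#' @return A `MethylationDataset`.
#' @export
read_dataset <- function(intensity_path, manifest_path,
                         controls_path = NULL, samples_path = NULL) {
  manifest <- read_manifest(manifest_path)
  ints <- read_tsv_strict(intensity_path, c("probe_id", "sample_id", "U", "M"),
                          "intensity")
  if (anyDuplicated(ints[c("probe_id", "sample_id")]))
    stop("duplicate probe_id/sample_id entries in intensity file", call. = FALSE)
  U <- long_to_matrix(ints, "U")
  M <- long_to_matrix(ints, "M")

  sample_ids <- colnames(U)
  if (!is.null(controls_path)) {
    ctl <- read_tsv_strict(controls_path, c("probe_id", "sample_id", "grn", "red"),
                           "controls")
    controls_grn <- long_to_matrix(ctl, "grn")
    controls_red <- long_to_matrix(ctl, "red")
    controls_grn <- controls_grn[, sample_ids, drop = FALSE]
    controls_red <- controls_red[, sample_ids, drop = FALSE]
  } else {
    controls_grn <- controls_red <-
      matrix(numeric(0), 0, length(sample_ids),
             dimnames = list(character(0), sample_ids))
  }

  if (!is.null(samples_path)) {
    samples <- read_tsv_strict(samples_path, "sample_id", "samples")
  } else {
    samples <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  }

  methylation_dataset(U, M, controls_grn, controls_red, samples, manifest)
}

#' Write a methylation dataset in the TSV interchange dialect
#'
#' Inverse of [read_dataset()]: integer intensities round-trip
#' bit-exactly.
#'
#' @param dataset a `MethylationDataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    intensities = file.path(dir, "intensities.tsv"),
    controls    = file.path(dir, "controls.tsv"),
    manifest    = file.path(dir, "manifest.tsv"),
    samples     = file.path(dir, "samples.tsv")
  )
  grid <- expand.grid(probe_id = rownames(dataset$U),
                      sample_id = colnames(dataset$U),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$U <- as.vector(dataset$U)
  grid$M <- as.vector(dataset$M)
  data.table::fwrite(grid, paths$intensities, sep = "\t", na = "", quote = FALSE)

  cgrid <- expand.grid(probe_id = rownames(dataset$controls_grn),
                       sample_id = colnames(dataset$controls_grn),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cgrid$grn <- as.vector(dataset$controls_grn)
  cgrid$red <- as.vector(dataset$controls_red)
  data.table::fwrite(cgrid, paths$controls, sep = "\t", na = "", quote = FALSE)

  data.table::fwrite(as.data.frame(dataset$manifest), paths$manifest,
                     sep = "\t", na = "", quote = FALSE)
  data.table::fwrite(dataset$samples, paths$samples, sep = "\t", na = "",
                     quote = FALSE)
  invisible(paths)
}
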