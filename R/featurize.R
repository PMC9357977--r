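#' Read a compound table
#'
#' Parses a CSV with columns `id,smiles,label` into a compound table.
#' Labels may be given as `active`/`inactive` or `1`/`0` and are mapped
#' to the internal +1/-1 coding (+1 = active).
#'
#' @param path path to a CSV file with header `id,smiles,label`.
#' @return a `data.frame` with columns `id` (character, unique),
#'   `smiles` (character) and `label` (integer, +1 or -1).
#' @export
read_compounds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "smiles", "label")
  if (!all(need %in% names(df))) {
    stop_forgenet(sprintf("compound CSV must have columns %s",
                          paste(need, collapse = ",")),
                  "forgenet_input_error")
  }
  if (anyDuplicated(df$id)) {
    stop_forgenet("compound ids must be unique", "forgenet_input_error")
  }
  lab <- tolower(trimws(df$label))
  y <- ifelse(lab %in% c("active", "1", "+1"), 1L,
              ifelse(lab %in% c("inactive", "0", "-1"), -1L, NA_integer_))
  if (anyNA(y)) {
    bad <- unique(df$label[is.na(y)])
    stop_forgenet(sprintf("unrecognised label token(s): %s",
                          paste(bad, collapse = ", ")),
                  "forgenet_input_error")
  }
  data.frame(id = df$id, smiles = df$smiles, label = y,
             stringsAsFactors = FALSE)
}

# Path to the frozen, ordered list of 208 two-dimensional descriptors.
descriptor_file <- function() {
  system.file("extdata", "rdkit_descriptors_208.txt", package = "forgenet",
              mustWork = TRUE)
}

#' Names of the frozen 2D descriptor block
#' @return character vector of length 208, in fused-column order.
#' @export
descriptor_names <- function() {
  readLines(descriptor_file())
}

find_python <- function() {
  py <- getOption("forgenet.python", Sys.which("python"))
  if (!nzchar(py)) {
    stop_forgenet("no python interpreter found on PATH (needed for SMILES featurization)",
                  "forgenet_featurize_error")
  }
  py
}

# One batched call to the RDKit bridge; returns the parsed JSON payload.
run_featurizer <- function(ids, smiles, ecfp_bits) {
  script <- system.file("python", "rdkit_features.py", package = "forgenet",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.csv(data.frame(id = ids, smiles = smiles), fin,
                   row.names = FALSE, quote = TRUE)
  status <- system2(find_python(),
                    c(shQuote(script), "--input", shQuote(fin),
                      "--output", shQuote(fout),
                      "--ecfp-bits", ecfp_bits,
                      "--desc-file", shQuote(descriptor_file())),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(fout)) {
    stop_forgenet(paste0("featurizer subprocess failed:\n",
                         paste(status, collapse = "\n")),
                  "forgenet_featurize_error")
  }
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

payload_to_blocks <- function(payload, ids, ecfp_bits) {
  if (length(payload$errors) > 0) {
    bad <- vapply(payload$errors, function(e) e$id, character(1))
    stop_forgenet(sprintf("unparsable SMILES for compound(s): %s",
                          paste(bad, collapse = ", ")),
                  "forgenet_featurize_error", ids = bad)
  }
  n <- length(payload$compounds)
  dn <- unlist(payload$descriptors)
  ecfp <- matrix(0, n, ecfp_bits)
  maccs <- matrix(0, n, 167L)
  rdk <- matrix(0, n, length(dn))
  got <- character(n)
  for (i in seq_len(n)) {
    cc <- payload$compounds[[i]]
    got[i] <- cc$id
    if (length(cc$ecfp)) ecfp[i, unlist(cc$ecfp) + 1L] <- 1
    if (length(cc$maccs)) maccs[i, unlist(cc$maccs) + 1L] <- 1
    rdk[i, ] <- unlist(cc$desc)
    if (!is.null(cc$nonfinite)) {
      warning(sprintf("non-finite descriptor(s) set to 0 for %s: %s",
                      cc$id, paste(unlist(cc$nonfinite), collapse = ", ")))
    }
  }
  stopifnot(identical(got, as.character(ids)))
  rownames(ecfp) <- rownames(maccs) <- rownames(rdk) <- ids
  colnames(ecfp) <- sprintf("ecfp6_%04d", seq_len(ecfp_bits) - 1L)
  colnames(maccs) <- sprintf("maccs_%03d", seq_len(167L) - 1L)
  colnames(rdk) <- paste0("rd_", dn)
  list(
    feature_block("ECFP6", ecfp),
    feature_block("MACCS", maccs),
    feature_block("RDKIT", rdk)
  )
}

#' Construct a named feature block
#'
#' @param name one of `"ECFP6"`, `"MACCS"`, `"RDKIT"`.
#' @param matrix numeric matrix, one row per compound; ECFP6/MACCS entries
#'   must be 0/1, RDKIT entries finite reals.
#' @return a `feature_block` object.
#' @export
feature_block <- function(name, matrix) {
  name <- match.arg(name, c("ECFP6", "MACCS", "RDKIT"))
  matrix <- as.matrix(matrix)
  if (name %in% c("ECFP6", "MACCS") && !all(matrix %in% c(0, 1))) {
    stop_forgenet(sprintf("%s block must be binary", name),
                  "forgenet_featurize_error")
  }
  if (name == "MACCS" && ncol(matrix) != 167L) {
    stop_forgenet("MACCS block must have 167 columns", "forgenet_featurize_error")
  }
  if (!all(is.finite(matrix))) {
    stop_forgenet(sprintf("%s block contains non-finite values", name),
                  "forgenet_featurize_error")
  }
  structure(list(name = name, matrix = matrix,
                 column_names = colnames(matrix)),
            class = "feature_block")
}

#' Fuse feature blocks into one matrix
#'
#' Concatenates the three blocks column-wise in the fixed order
#' (ECFP6, MACCS, RDKIT) and records the block boundaries so every fused
#' column maps back to exactly one (block, index) pair. The RDKIT span
#' can be z-scored; when `stats` is supplied (means/sds fitted on
#' training rows) those statistics are applied instead of refitting, so
#' test data never leaks into the scaling.
#'
#' @param blocks list of `feature_block`s in (ECFP6, MACCS, RDKIT) order.
#' @param labels optional +1/-1 vector, one per row.
#' @param standardize z-score the RDKIT span (default TRUE).
#' @param stats optional list(mean=, sd=) from a previous fuse.
#' @return a `fused_features` object: `matrix`, `blocks` (name, start,
#'   end), `labels`, and (if standardized) `rdkit_stats`.
#' @export
fuse_blocks <- function(blocks, labels = NULL, standardize = TRUE,
                        stats = NULL) {
  if (!all(vapply(blocks, inherits, logical(1), "feature_block"))) {
    stop_forgenet("blocks must be feature_block objects", "forgenet_fusion_error")
  }
  ord <- vapply(blocks, function(b) b$name, character(1))
  if (!identical(ord, c("ECFP6", "MACCS", "RDKIT"))) {
    stop_forgenet("blocks must be supplied in (ECFP6, MACCS, RDKIT) order",
                  "forgenet_fusion_error")
  }
  ns <- vapply(blocks, function(b) nrow(b$matrix), integer(1))
  if (length(unique(ns)) != 1L) {
    stop_forgenet(sprintf("row-count mismatch across blocks: %s",
                          paste(ns, collapse = "/")),
                  "forgenet_fusion_error")
  }
  mat <- do.call(cbind, lapply(blocks, function(b) b$matrix))
  widths <- vapply(blocks, function(b) ncol(b$matrix), integer(1))
  ends <- cumsum(widths)
  spans <- data.frame(name = ord, start = c(1L, ends[-3] + 1L), end = ends,
                      stringsAsFactors = FALSE)
  rdkit_stats <- NULL
  if (standardize) {
    idx <- spans$start[3]:spans$end[3]
    if (is.null(stats)) {
      mu <- colMeans(mat[, idx, drop = FALSE])
      sd <- apply(mat[, idx, drop = FALSE], 2, stats::sd)
      sd[!is.finite(sd) | sd == 0] <- 1
      stats <- list(mean = mu, sd = sd)
    }
    mat[, idx] <- sweep(sweep(mat[, idx, drop = FALSE], 2, stats$mean), 2,
                        stats$sd, "/")
    rdkit_stats <- stats
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(mat) || !all(labels %in% c(-1L, 1L))) {
      stop_forgenet("labels must be one +1/-1 value per row",
                    "forgenet_fusion_error")
    }
  }
  structure(list(matrix = mat, blocks = spans, labels = labels,
                 rdkit_stats = rdkit_stats),
            class = "fused_features")
}

#' @export
print.fused_features <- function(x, ...) {
  cat(sprintf("fused_features: %d compounds x %d features (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s=%d", x$blocks$name,
                            x$blocks$end - x$blocks$start + 1L),
                    collapse = " | ")))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d active / %d inactive\n",
                sum(x$labels == 1), sum(x$labels == -1)))
  }
  invisible(x)
}

#' Map a fused column index back to its (block, within-block index)
#' @param fused a `fused_features` object.
#' @param j fused column index (1-based).
#' @return list(block=, index=) with `index` 1-based within the block.
#' @export
column_provenance <- function(fused, j) {
  b <- fused$blocks
  k <- which(j >= b$start & j <= b$end)
  if (length(k) != 1L) {
    stop_forgenet("column index out of range", "forgenet_input_error")
  }
  list(block = b$name[k], index = as.integer(j) - b$start[k] + 1L)
}

#' Featurize compounds into the fused matrix
#'
#' Computes the three blocks (ECFP6 circular fingerprint of radius 3
#' hashed to `ecfp_bits`, 167 MACCS structural keys, and the frozen
#' 208-descriptor 2D block) for every compound and fuses them. Empty or
#' unparsable SMILES raise a featurization error naming the offending
#' ids; non-finite descriptor values are replaced by 0 with a warning.
#'
#' @param compounds a data.frame from [read_compounds()] (columns id,
#'   smiles, label) or with at least id and smiles.
#' @param ecfp_bits ECFP6 width (default 2048, giving 2423 fused columns).
#' @param standardize,stats passed to [fuse_blocks()].
#' @return a `fused_features` object with row names = compound ids.
#' @export
featurize_compounds <- function(compounds, ecfp_bits = 2048L,
                                standardize = TRUE, stats = NULL) {
  ids <- as.character(compounds$id)
  smiles <- as.character(compounds$smiles)
  payload <- run_featurizer(ids, smiles, ecfp_bits)
  blocks <- payload_to_blocks(payload, ids, ecfp_bits)
  fuse_blocks(blocks, labels = compounds$label, standardize = standardize,
              stats = stats)
}

#' ECFP6 fingerprint of a single SMILES
#'
#' Circular (Morgan) fingerprint of radius 3 — diameter 6 — hashed to
#' `n_bits` and collapsed to presence/absence bits.
#'
#' @param smiles a SMILES string.
#' @param n_bits fingerprint width (default 2048).
#' @return 0/1 integer vector of length `n_bits`.
#' @export
compute_ecfp6 <- function(smiles, n_bits = 2048L) {
  payload <- run_featurizer("x", smiles, n_bits)
  if (length(payload$errors)) {
    stop_forgenet(sprintf("unparsable SMILES: %s", smiles),
                  "forgenet_featurize_error")
  }
  v <- integer(n_bits)
  v[unlist(payload$compounds[[1]]$ecfp) + 1L] <- 1L
  v
}

#' MACCS keys of a single SMILES
#' @param smiles a SMILES string.
#' @return 0/1 integer vector of length 167.
#' @export
compute_maccs <- function(smiles) {
  payload <- run_featurizer("x", smiles, 32L)
  if (length(payload$errors)) {
    stop_forgenet(sprintf("unparsable SMILES: %s", smiles),
                  "forgenet_featurize_error")
  }
  v <- integer(167L)
  v[unlist(payload$compounds[[1]]$maccs) + 1L] <- 1L
  v
}

#' 2D descriptor block of a single SMILES
#'
#' Evaluates the frozen ordered list of 208 two-dimensional
#' physicochemical descriptors; non-finite values are replaced by 0 with
#' a warning.
#'
#' @param smiles a SMILES string.
#' @return named numeric vector of length 208.
#' @export
compute_rdkit_block <- function(smiles) {
  payload <- run_featurizer("x", smiles, 32L)
  if (length(payload$errors)) {
    stop_forgenet(sprintf("unparsable SMILES: %s", smiles),
                  "forgenet_featurize_error")
  }
  cc <- payload$compounds[[1]]
  if (!is.null(cc$nonfinite)) {
    warning(sprintf("non-finite descriptor(s) set to 0: %s",
                    paste(unlist(cc$nonfinite), collapse = ", ")))
  }
  stats::setNames(unlist(cc$desc), unlist(payload$descriptors))
}

#' Write a fused feature matrix to TSV + JSON manifest
#'
#' The TSV has an `id` column plus one column per fused feature; the
#' sidecar manifest (same path with `.json` appended) records block
#' boundaries, descriptor-list length, labels and standardization stats.
#'
#' @param fused a `fused_features` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fused, path) {
  df <- data.frame(id = rownames(fused$matrix) %||%
                     as.character(seq_len(nrow(fused$matrix))),
                   fused$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(blocks = fused$blocks, labels = fused$labels,
                   n_descriptors = fused$blocks$end[3] - fused$blocks$start[3] + 1L,
                   rdkit_stats = fused$rdkit_stats)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a fused feature matrix written by [write_features()]
#' @param path TSV path (manifest expected at `paste0(path, ".json")`).
#' @return a `fused_features` object.
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$id
  stats <- man$rdkit_stats
  if (!is.null(stats)) stats <- list(mean = stats$mean, sd = stats$sd)
  structure(list(matrix = mat,
                 blocks = as.data.frame(man$blocks),
                 labels = if (is.null(man$labels)) NULL else as.integer(man$labels),
                 rdkit_stats = stats),
            class = "fused_features")
}
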