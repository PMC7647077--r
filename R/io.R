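## plain-text serialization: TSV matrices with JSON sidecars

write_tsv_matrix <- function(M, path, id_col = "gene_id") {
  df <- data.frame(rownames(M), apply(M, 2L, fmt_num), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(M))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path, id_col = "gene_id") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  ids <- df[[1L]]
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  M
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an expression dataset as TSV plus JSON sidecar
#'
#' The TSV holds the genes x samples matrix (first column gene ID, header
#' row sample IDs); the sidecar carries the modulator, gene roles, optional
#' tissue labels and, for synthetic data, the edge profile map.
#'
#' @param data an [expression_dataset()].
#' @param path TSV output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param profiles optional profile map to record (synthetic ground truth).
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path, profiles = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  write_tsv_matrix(data$values, path)
  side <- list(sample_ids = data$sample_ids,
               modulator = fmt_num(data$modulator),
               gene_ids = data$gene_ids, roles = data$roles)
  if (!is.null(data$tissue)) side$tissue <- data$tissue
  if (!is.null(profiles)) side$profiles <- lapply(profiles, unclass)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an expression dataset written by [write_expression()]
#'
#' Validates the container invariants on load: no missing cells, matching
#' modulator length, no duplicate gene IDs; errors name the offending gene
#' and sample.
#'
#' @param path TSV path (sidecar expected next to it).
#' @return an [expression_dataset()]; any recorded profile map is attached
#'   as attribute `"profiles"`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_invalid("missing JSON sidecar: %s", sp)
  M <- read_tsv_matrix(path)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(side$modulator)) stop_invalid("sidecar lacks the modulator")
  modulator <- as.numeric(side$modulator)
  if (length(modulator) != ncol(M))
    stop_invalid("sidecar modulator length (%d) does not match %d samples",
                 length(modulator), ncol(M))
  data <- expression_dataset(values = M, gene_ids = side$gene_ids,
                             roles = side$roles, modulator = modulator,
                             sample_ids = side$sample_ids,
                             tissue = side$tissue)
  if (!is.null(side$profiles)) {
    profs <- lapply(side$profiles, function(p)
      coef_profile(p$kind, p$baseline, p$shifted, p$changepoint, p$steepness))
    attr(data, "profiles") <- profs
  }
  data
}

#' Write a network tensor as long-format TSV plus JSON sidecar
#'
#' Nonzero coefficients go to a (target, regulator, sample, coefficient)
#' TSV; dimensions, ID vectors, intercepts, modulator and fit settings go
#' to the sidecar. Values are written with 17 significant digits so the
#' round trip is exact.
#'
#' @param tensor a [build_network_tensor()] result.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_network_tensor <- function(tensor, path) {
  nz <- which(tensor$coefficients != 0, arr.ind = TRUE)
  df <- data.frame(
    target = tensor$target_ids[nz[, 1L]],
    regulator = tensor$regulator_ids[nz[, 2L]],
    sample = tensor$sample_ids[nz[, 3L]],
    coefficient = fmt_num(tensor$coefficients[nz]),
    stringsAsFactors = FALSE)
  df <- df[order(df$target, df$regulator, df$sample), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(target_ids = tensor$target_ids,
               regulator_ids = tensor$regulator_ids,
               sample_ids = tensor$sample_ids,
               modulator = fmt_num(tensor$modulator),
               intercepts = apply(tensor$intercepts, 2L, fmt_num),
               bandwidth = tensor$bandwidth,
               penalty = unclass(tensor$penalty))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a network tensor written by [write_network_tensor()]
#'
#' @param path TSV path (sidecar expected next to it).
#' @return an object of class `"network_tensor"`.
#' @export
read_network_tensor <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_invalid("missing JSON sidecar: %s", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "character"))
  I1 <- length(side$target_ids); I2 <- length(side$regulator_ids)
  n <- length(side$sample_ids)
  coefs <- array(0, dim = c(I1, I2, n),
                 dimnames = list(side$target_ids, side$regulator_ids,
                                 side$sample_ids))
  if (nrow(df) > 0)
    coefs[cbind(match(df$target, side$target_ids),
                match(df$regulator, side$regulator_ids),
                match(df$sample, side$sample_ids))] <- as.numeric(df$coefficient)
  intercepts <- matrix(as.numeric(side$intercepts), I1, n,
                       dimnames = list(side$target_ids, side$sample_ids))
  penalty <- penalty_spec(side$penalty$lambda, side$penalty$alpha,
                          side$penalty$recursion_steps,
                          side$penalty$weight_floor)
  structure(list(coefficients = coefs, intercepts = intercepts,
                 modulator = as.numeric(side$modulator),
                 target_ids = side$target_ids,
                 regulator_ids = side$regulator_ids,
                 sample_ids = side$sample_ids,
                 bandwidth = side$bandwidth, penalty = penalty),
            class = "network_tensor")
}

#' Write per-sample component scores as TSV
#'
#' @param comps a [component_scores()] result.
#' @param sample_ids sample identifiers (row order of the score matrix).
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_component_scores <- function(comps, sample_ids, path) {
  stopifnot(inherits(comps, "component_scores"))
  pc <- comps$pc_scores
  M <- cbind(t(comps$matrix), pc)
  colnames(M) <- c(sprintf("dim_%d", seq_len(nrow(comps$matrix))),
                   sprintf("pc_%d", seq_len(ncol(pc))))
  rownames(M) <- sample_ids
  write_tsv_matrix(M, path, id_col = "sample_id")
  jsonlite::write_json(
    list(mode = comps$mode,
         variance_explained = fmt_num(comps$variance_explained)),
    sidecar_path(path), auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read component scores written by [write_component_scores()]
#'
#' @param path TSV path.
#' @return list with `scores` (sample x pc matrix), `vectors` (normalized
#'   per-sample dimensions), `variance_explained`, `mode`.
#' @export
read_component_scores <- function(path) {
  M <- read_tsv_matrix(path, id_col = "sample_id")
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pc_cols <- grep("^pc_", colnames(M))
  list(scores = M[, pc_cols, drop = FALSE],
       vectors = M[, -pc_cols, drop = FALSE],
       variance_explained = as.numeric(side$variance_explained),
       mode = side$mode)
}
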