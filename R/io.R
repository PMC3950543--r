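#' Write a relaxation dataset to a directory of CSV traces
#'
#' One CSV per sample x strain combination (columns `time_s`, `strain`,
#' `stress_MPa`) plus a `manifest.json` recording per-trace metadata
#' (sample, donor, strain level), the stress measure, the generation seed
#' and — when the dataset is synthetic — the generating truth, so every
#' artifact is regenerable from its provenance record.
#'
#' @param dataset A `relaxation_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_traces <- function(dataset, dir) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traces <- dataset_traces(dataset, keep_meta = TRUE)
  entries <- list()
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    file <- sprintf("trace_%s_e%03.0f.csv", attr(tr, "sample_id"),
                    1000 * attr(tr, "strain_level"))
    utils::write.csv(as.data.frame(tr[, c("time_s", "strain", "stress_MPa")]),
                     file.path(dir, file), row.names = FALSE)
    entries[[length(entries) + 1]] <- list(
      file = file, sample_id = attr(tr, "sample_id"),
      donor_id = attr(tr, "donor_id"),
      strain_level = attr(tr, "strain_level"))
  }
  truth <- attr(dataset, "truth")
  manifest <- list(
    measure = attr(dataset, "measure"),
    seed = attr(dataset, "seed"),
    traces = entries)
  if (!is.null(truth)) {
    manifest$truth <- list(
      hp = truth$hp[c("mu", "k", "alpha")],
      prony = list(gamma = truth$ps$gamma, tau_s = truth$ps$tau))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a directory of relaxation traces
#'
#' Validates and reassembles a `relaxation_dataset` written by
#' [write_traces()]: every manifest entry must have its CSV, headers must
#' be exactly `time_s, strain, stress_MPa`, times must be strictly
#' increasing and stresses non-negative.
#'
#' @param dir Directory containing trace CSVs and `manifest.json`.
#' @return A `relaxation_dataset`.
#' @export
read_traces <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!dir.exists(dir) || !file.exists(manifest_path)) {
    stop("no traces found: missing directory or manifest.json in ", dir,
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  entries <- manifest$traces
  if (is.null(entries) || NROW(entries) == 0) {
    stop("no traces found: empty manifest in ", dir, call. = FALSE)
  }
  entries <- as.data.frame(entries)
  rows <- list()
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    path <- file.path(dir, e$file)
    if (!file.exists(path)) {
      stop("manifest/sample mismatch: listed trace file missing: ", e$file,
           call. = FALSE)
    }
    d <- utils::read.csv(path)
    if (!identical(names(d), c("time_s", "strain", "stress_MPa"))) {
      stop("malformed header in ", e$file,
           " (expected time_s, strain, stress_MPa)", call. = FALSE)
    }
    if (any(diff(d$time_s) <= 0)) {
      stop("non-monotone time in ", e$file, " near row ",
           which(diff(d$time_s) <= 0)[1] + 1, call. = FALSE)
    }
    if (any(d$stress_MPa < 0)) {
      stop("negative stress in ", e$file, " at row ",
           which(d$stress_MPa < 0)[1], call. = FALSE)
    }
    rows[[i]] <- tibble::tibble(
      donor_id = e$donor_id, sample_id = e$sample_id,
      strain_level = e$strain_level, time_s = d$time_s,
      strain = d$strain, stress_MPa = d$stress_MPa)
  }
  extra <- setdiff(list.files(dir, pattern = "^trace_.*\\.csv$"),
                   entries$file)
  if (length(extra) > 0) {
    stop("manifest/sample mismatch: orphan trace file not in manifest: ",
         extra[1], call. = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "measure") <- if (is.null(manifest$measure)) "nominal" else
    manifest$measure
  attr(out, "seed") <- manifest$seed
  if (!is.null(manifest$truth)) {
    attr(out, "truth") <- list(
      hp = hyperelastic_params(manifest$truth$hp$mu, manifest$truth$hp$k,
                               manifest$truth$hp$alpha),
      ps = prony_series(manifest$truth$prony$gamma,
                        manifest$truth$prony$tau_s))
  }
  class(out) <- c("relaxation_dataset", class(out))
  out
}
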