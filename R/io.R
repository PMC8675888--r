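#' @include ic-model.R
NULL

## On-disk interchange dialect (all plain text, UTF-8, '.' decimal, comma
## separated, header rows):
##   components.csv  component_id, subject_id, n_epochs, n_samples,
##                   sampling_rate, signal_file
##   weights.csv     component_id + one column per channel; the header
##                   declares the canonical channel order of the dataset
##   signals/<id>.csv  epochs x samples, no header
## Annotation tables: component_id, expert_id, labels (';'-separated
## vocabulary tokens), comment.

#' Save a dataset of independent components to a directory
#'
#' Writes the plain-text interchange layout: a component manifest, one
#' weights table whose header fixes the channel order, and one
#' epochs x samples signal file per component. \code{loadDataset} of the
#' result reproduces the dataset field-by-field within write precision
#' (>= 12 significant digits for weights, >= 6 for signals; 15 are
#' written).
#'
#' @param ds an \linkS4class{ICDataset}.
#' @param path directory to create/overwrite into.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{loadDataset}}
#' @export
saveDataset <- function(ds, path) {
  stopifnot(is(ds, "ICDataset"))
  validObject(ds)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  ids <- componentIds(ds)
  manifest <- data.frame(
    component_id = ids,
    subject_id = vapply(ds@components, function(c) c@subjectId, character(1)),
    n_epochs = vapply(ds@components, nEpochs, integer(1)),
    n_samples = vapply(ds@components, function(c) ncol(c@signal), integer(1)),
    sampling_rate = vapply(ds@components, samplingRate, numeric(1)),
    signal_file = if (length(ids)) file.path("signals", paste0(ids, ".csv"))
                  else character(),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(path, "components.csv"),
                   row.names = FALSE)
  chans <- channelLabels(ds)
  w <- do.call(rbind, lapply(ds@components, function(c) c@weights))
  wdf <- data.frame(component_id = ids, stringsAsFactors = FALSE)
  if (length(chans))
    for (j in seq_along(chans))
      wdf[[chans[j]]] <- if (length(ids)) w[, j] else numeric()
  data.table::fwrite(wdf, file.path(path, "weights.csv"))
  if (length(ids)) {
    dir.create(file.path(path, "signals"), showWarnings = FALSE)
    for (c in ds@components)
      data.table::fwrite(data.table::as.data.table(c@signal),
                         file.path(path, "signals",
                                   paste0(c@componentId, ".csv")),
                         col.names = FALSE)
  }
  if (length(ds@metadata))
    jsonlite::write_json(ds@metadata, file.path(path, "metadata.json"),
                         auto_unbox = TRUE)
  invisible(path)
}

#' Load a dataset of independent components from a directory
#'
#' Reads the interchange layout written by \code{\link{saveDataset}}.
#' Channel order is normalised to the order declared by the weights-table
#' header; weight rows may appear in any order (matched by component id).
#'
#' @param path directory containing \code{components.csv},
#'   \code{weights.csv} and \code{signals/}.
#' @return a validated \linkS4class{ICDataset}.
#' @export
loadDataset <- function(path) {
  manifestFile <- file.path(path, "components.csv")
  weightsFile <- file.path(path, "weights.csv")
  for (f in c(manifestFile, weightsFile))
    if (!file.exists(f)) stop("missing file: ", f)
  manifest <- utils::read.csv(manifestFile, stringsAsFactors = FALSE,
                              colClasses = c(component_id = "character",
                                             subject_id = "character"))
  wdf <- data.table::fread(weightsFile, data.table = FALSE,
                           colClasses = list(character = "component_id"))
  chans <- setdiff(names(wdf), "component_id")
  missingW <- setdiff(manifest$component_id, wdf$component_id)
  if (length(missingW))
    stop("weights table lacks rows for components: ",
         paste(missingW, collapse = ", "))
  comps <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$component_id[i]
    wrow <- as.numeric(wdf[match(id, wdf$component_id), chans])
    if (anyNA(wrow))
      stop("non-numeric or missing weights for component ", id,
           " (channels: ",
           paste(chans[is.na(wrow)], collapse = ", "), ")")
    sigFile <- file.path(path, manifest$signal_file[i])
    if (!file.exists(sigFile)) stop("missing file: ", sigFile)
    sig <- as.matrix(data.table::fread(sigFile, header = FALSE,
                                       data.table = FALSE))
    dimnames(sig) <- NULL
    if (nrow(sig) != manifest$n_epochs[i] || ncol(sig) != manifest$n_samples[i])
      stop(sprintf("component %s: signal is %dx%d, manifest declares %dx%d",
                   id, nrow(sig), ncol(sig),
                   manifest$n_epochs[i], manifest$n_samples[i]))
    if (!all(is.finite(sig)) || !all(is.finite(wrow)))
      stop("non-finite values in component ", id)
    comps[[i]] <- ICComponent(id, manifest$subject_id[i], chans, wrow, sig,
                              manifest$sampling_rate[i])
  }
  metaFile <- file.path(path, "metadata.json")
  meta <- if (file.exists(metaFile)) jsonlite::read_json(metaFile) else list()
  ds <- ICDataset(comps, meta)
  validObject(ds)
  ds
}

#' Read / write multi-expert annotation tables
#'
#' The table format is delimited text with columns \code{component_id},
#' \code{expert_id}, \code{labels} (semicolon-separated tokens from the
#' annotation vocabulary) and optional \code{comment}.
#'
#' @param path file path.
#' @return \code{readAnnotations}: a data.frame with list-column
#'   \code{labels}; one row per (component, expert).
#' @seealso \code{\link{annotationVocabulary}}
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("component_id", "expert_id", "labels")
  if (!all(need %in% names(df)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$comment)) df$comment <- ""
  ann <- data.frame(component_id = df$component_id,
                    expert_id = df$expert_id,
                    comment = df$comment, stringsAsFactors = FALSE)
  ann$labels <- lapply(strsplit(df$labels, ";", fixed = TRUE), trimws)
  .checkAnnotations(ann)
  ann[c("component_id", "expert_id", "labels", "comment")]
}

#' @rdname readAnnotations
#' @param ann annotation data.frame as returned by \code{readAnnotations}
#'   (or built in code: columns component_id, expert_id, labels
#'   list-column, optional comment).
#' @export
writeAnnotations <- function(ann, path) {
  .checkAnnotations(ann)
  out <- data.frame(
    component_id = ann$component_id,
    expert_id = ann$expert_id,
    labels = vapply(ann$labels, paste, character(1), collapse = ";"),
    comment = if (is.null(ann$comment)) "" else ann$comment,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
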