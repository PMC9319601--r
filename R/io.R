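# Dataset containers: HDF5 read/write (and MATLAB v7.3 reading, which is
# HDF5 underneath). Layout: /subject_SS/trial_TT groups with a `samples`
# dataset (channels x samples) and `label`, `fs`, `channels`, `subject`,
# `trial` datasets alongside.

#' Write an EEG dataset to an HDF5 container
#'
#' @param recordings an \linkS4class{EEGDataset} (or list of
#'   \linkS4class{EEGRecording}).
#' @param path output file path (overwritten).
#' @param format container format; \code{"hdf5"} is supported. MATLAB v7
#'   containers are read-side only (v7.3 files are HDF5 and go through the
#'   same reader); requesting \code{"mat"} here is an error.
#' @return \code{path}, invisibly.
#' @export
writeDataset <- function(recordings, path, format = c("hdf5", "mat")) {
  format <- match.arg(format)
  if (format == "mat")
    stop("writing MATLAB containers is not supported; use format = \"hdf5\" ",
         "(MATLAB >= v7.3 readers open HDF5 files directly)")
  if (length(recordings) == 0L) stop("empty recording collection")
  recordings <- as.list(recordings)
  ok <- vapply(recordings, is, logical(1), class2 = "EEGRecording")
  if (!all(ok)) stop("all elements must be EEGRecording objects")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  seen <- character(0)
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    g <- sprintf("subject_%02d", rec@subjectId)
    if (!g %in% seen) {
      rhdf5::h5createGroup(path, g)
      seen <- c(seen, g)
    }
    tg <- sprintf("%s/trial_%03d_%s", g, rec@trialId, as.character(rec@label))
    rhdf5::h5createGroup(path, tg)
    rhdf5::h5write(i, path, paste0(tg, "/order"))
    rhdf5::h5write(rec@samples, path, paste0(tg, "/samples"))
    rhdf5::h5write(as.character(rec@label), path, paste0(tg, "/label"))
    rhdf5::h5write(rec@samplingRate, path, paste0(tg, "/fs"))
    rhdf5::h5write(rownames(rec@samples), path, paste0(tg, "/channels"))
    rhdf5::h5write(rec@subjectId, path, paste0(tg, "/subject"))
    rhdf5::h5write(rec@trialId, path, paste0(tg, "/trial"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an EEG dataset from an HDF5 (or MATLAB v7.3) container
#'
#' Reads the group layout written by \code{\link{writeDataset}}. A group
#' missing its \code{label} entry raises a schema error naming the group.
#'
#' @param path input file.
#' @param format "hdf5" or "mat" (MATLAB v7.3 files are HDF5 containers and
#'   are parsed identically; pre-7.3 MAT files are not supported).
#' @return An \linkS4class{EEGDataset}.
#' @export
readDataset <- function(path, format = c("hdf5", "mat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  ls <- rhdf5::h5ls(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  groups <- ls$group[ls$name == "samples" & ls$otype == "H5I_DATASET"]
  if (length(groups) == 0L)
    stop("malformed container: no */samples datasets found")
  groups <- sort(groups)
  # restore the original write order when the index is present
  hasOrder <- all(groups %in% ls$group[ls$name == "order"])
  if (hasOrder) {
    ord <- vapply(groups, function(g)
      as.numeric(rhdf5::h5read(path, paste0(g, "/order"))), numeric(1))
    groups <- groups[order(ord)]
  }
  recs <- lapply(groups, function(g) {
    inGroup <- ls$name[ls$group == g]
    if (!"label" %in% inGroup)
      stop(sprintf("schema error: group '%s' has no 'label' entry", g))
    samples <- as.matrix(rhdf5::h5read(path, paste0(g, "/samples")))
    lab <- as.character(rhdf5::h5read(path, paste0(g, "/label")))
    if (!lab %in% emotionLevels())
      stop(sprintf("unknown label code '%s' in group '%s'", lab, g))
    fs <- as.numeric(rhdf5::h5read(path, paste0(g, "/fs")))
    if ("channels" %in% inGroup)
      rownames(samples) <- as.character(rhdf5::h5read(path,
                                                      paste0(g, "/channels")))
    sid <- if ("subject" %in% inGroup)
      as.integer(rhdf5::h5read(path, paste0(g, "/subject"))) else 1L
    tid <- if ("trial" %in% inGroup)
      as.integer(rhdf5::h5read(path, paste0(g, "/trial"))) else 1L
    EEGRecording(samples, fs, lab, sid, tid)
  })
  EEGDataset(recs)
}
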