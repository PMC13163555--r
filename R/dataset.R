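#' Load a 3D MRI volume from NIfTI
#'
#' Reads a `.nii` / `.nii.gz` file into a plain 3D numeric array; axial
#' slices are addressed by the third index. The affine is ignored beyond
#' axis identification.
#'
#' @param path path to an existing NIfTI file containing a 3D volume.
#' @return 3D numeric array.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(img)), " dimension(s): ",
         path)
  }
  array(as.double(img), dim(img))   # plain array, image metadata dropped
}

#' Write a 3D volume to NIfTI
#'
#' @param volume 3D numeric array.
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(length(dim(volume)) == 3L)
  RNifti::writeNifti(RNifti::asNifti(volume), path, datatype = "double")
  invisible(path)
}

#' Write a volume as a directory of PNG slices
#'
#' Each axial slice is stored as an 8-bit grayscale PNG named
#' `slice_###.png`, with intensities divided by `scale`. Intensities are
#' clamped to `[0, scale]`; integer-valued volumes with `scale = 255`
#' round-trip exactly.
#'
#' @param volume 3D numeric array.
#' @param dir destination directory (created if needed).
#' @param scale intensity mapped to white, default 255.
#' @return `dir`, invisibly.
#' @export
write_png_slices <- function(volume, dir, scale = 255) {
  stopifnot(length(dim(volume)) == 3L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_len(dim(volume)[3])) {
    m <- pmin(pmax(volume[, , k] / scale, 0), 1)
    png::writePNG(m, file.path(dir, sprintf("slice_%03d.png", k)))
  }
  invisible(dir)
}

#' Load a directory of PNG slices as a volume
#'
#' Reads every `*.png` in `dir` (sorted by filename), multiplies intensities
#' back by `scale`, and stacks them into a 3D array. RGB(A) images are
#' collapsed to their first channel.
#'
#' @param dir directory of PNG slices.
#' @param scale intensity scale used when writing, default 255.
#' @return 3D numeric array.
#' @export
load_png_slices <- function(dir, scale = 255) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG slices found in: ", dir)
  slices <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * scale
  })
  array(unlist(slices), c(dim(slices[[1]]), length(slices)))
}

#' Write a phantom dataset to disk with a manifest
#'
#' Serializes each subject's volume (and lesion mask, when any voxel is
#' set) to NIfTI and writes a `manifest.csv` with columns `subject_id`,
#' `modality`, `label_binary`, `label_severity`, `path`, `mask_path`.
#'
#' @param subjects list of subject records from [generate_dataset()].
#' @param dir destination directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_dataset <- function(subjects, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(subjects, function(s) {
    vpath <- file.path(dir, paste0(s$subject_id, ".nii.gz"))
    write_volume(s$volume, vpath)
    mpath <- NA_character_
    if (any(s$lesion_mask)) {
      mpath <- file.path(dir, paste0(s$subject_id, "_mask.nii.gz"))
      write_volume(array(as.numeric(s$lesion_mask), dim(s$lesion_mask)), mpath)
    }
    data.frame(subject_id = s$subject_id, modality = s$modality,
               label_binary = s$label_binary,
               label_severity = s$label_severity,
               path = vpath, mask_path = mpath,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read a dataset back from a manifest
#'
#' @param manifest_path path to a `manifest.csv` written by
#'   [write_dataset()].
#' @return List of subject records (lesion masks are reloaded when present,
#'   otherwise all-FALSE).
#' @export
read_dataset <- function(manifest_path) {
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(m)), function(i) {
    vol <- load_volume(m$path[i])
    les <- if (!is.na(m$mask_path[i])) {
      load_volume(m$mask_path[i]) > 0.5
    } else {
      array(FALSE, dim(vol))
    }
    structure(list(subject_id = m$subject_id[i], modality = m$modality[i],
                   label_binary = m$label_binary[i],
                   label_severity = m$label_severity[i],
                   volume = vol, lesion_mask = les),
              class = "subject_record")
  })
}

#' Subject-wise grouped stratified fold assignment
#'
#' Assigns whole subjects to `n_folds` folds so that no subject's slices
#' can ever straddle a split (the anti-leakage rule), while balancing the
#' per-class subject counts across folds. Subjects are shuffled by `seed`
#' and greedily assigned, per class, to the currently least-loaded fold
#' (ties broken by lowest fold index), which keeps every fold's class count
#' within one of the ideal balance.
#'
#' @param subjects data frame with columns `subject_id` and `label` (one
#'   row per subject), or a list of subject records.
#' @param n_folds number of folds, default 5; every class must contribute
#'   at least `n_folds` subjects.
#' @param seed integer seed controlling the shuffle.
#' @return Object of class `split_assignment`: list with `fold` (named
#'   integer vector, subject_id -> fold in `1:n_folds`) and `n_folds`.
#' @export
subject_stratified_split <- function(subjects, n_folds = 5L, seed = 1L) {
  if (is.list(subjects) && !is.data.frame(subjects)) {
    subjects <- data.frame(
      subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
      label = vapply(subjects, function(s) {
        if (is.na(s$label_severity)) s$label_binary else s$label_severity
      }, character(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("subject_id", "label") %in% names(subjects)))
  if (anyDuplicated(subjects$subject_id)) {
    stop("'subjects' must have one row per subject")
  }
  n_folds <- as.integer(n_folds)
  counts <- table(subjects$label)
  if (any(counts < n_folds)) {
    stop("every class needs at least ", n_folds, " subjects; got: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  set.seed(seed)
  ord <- sample.int(nrow(subjects))
  fold <- integer(nrow(subjects))
  names(fold) <- subjects$subject_id
  load <- matrix(0L, n_folds, length(counts),
                 dimnames = list(NULL, names(counts)))
  for (i in ord) {
    cls <- subjects$label[i]
    f <- which.min(load[, cls])      # lowest index wins ties
    fold[subjects$subject_id[i]] <- f
    load[f, cls] <- load[f, cls] + 1L
  }
  structure(list(fold = fold, n_folds = n_folds), class = "split_assignment")
}

#' Train/validation/test roles for one cross-validation round
#'
#' Round `r` uses fold `r` as the test set, the next fold (cyclically) as
#' the dedicated validation set, and the remaining folds for training, so
#' all three roles stay subject-exclusive and each fold is the test set
#' exactly once across the `n_folds` rounds.
#'
#' @param split a `split_assignment` from [subject_stratified_split()].
#' @param round round index in `1:n_folds`.
#' @return List with character vectors `train`, `validation`, `test` of
#'   subject ids.
#' @export
fold_roles <- function(split, round) {
  stopifnot(inherits(split, "split_assignment"),
            round >= 1L, round <= split$n_folds)
  k <- split$n_folds
  test_f <- round
  val_f <- (round %% k) + 1L
  ids <- names(split$fold)
  list(train = ids[!split$fold %in% c(test_f, val_f)],
       validation = ids[split$fold == val_f],
       test = ids[split$fold == test_f])
}

#' Write a split assignment as JSON
#'
#' @param split a `split_assignment`.
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(as.list(split$fold), path, auto_unbox = TRUE)
  invisible(path)
}
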