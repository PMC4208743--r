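#' @importFrom RNifti readNifti writeNifti xform
#' @importFrom stats sd cor var
NULL

#' Construct a volume geometry descriptor
#'
#' Holds the spatial frame shared by all volumes in an analysis: grid shape,
#' voxel size in mm, and the 4x4 affine mapping voxel indices to world mm.
#'
#' @param shape integer(3), voxels per axis.
#' @param voxel_size_mm numeric(3), voxel edge lengths in mm.
#' @param affine 4x4 numeric matrix; if `NULL`, a diagonal affine built from
#'   `voxel_size_mm` is used.
#' @return An object of class `volume_geometry`.
#' @export
volume_geometry <- function(shape, voxel_size_mm, affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- unname(as.matrix(affine))
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps * 100) {
    stop("affine matrix is singular")
  }
  colnorm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(colnorm - voxel_size_mm) > 1e-6)) {
    stop("voxel_size_mm inconsistent with affine column norms")
  }
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 affine = affine),
            class = "volume_geometry")
}

#' Convert a logical/numeric 3D mask to in-mask linear indices
#'
#' Linear indices are 1-based in R's native column-major order over (x, y, z).
#'
#' @param mask 3D array, non-zero = in mask.
#' @return integer vector of in-mask linear indices.
#' @export
mask_to_index <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("mask is empty (no in-mask voxels)")
  idx
}

#' Read a 4D NIfTI volume into a masked voxels-by-time matrix
#'
#' Loads a 4D series, checks its grid against the mask geometry, discards the
#' first `n_discard` volumes (dummy scans acquired before steady state), and
#' returns the in-mask data as a voxels x time matrix.
#'
#' @param path path to a 4D NIfTI-1 file.
#' @param mask 3D array mask (non-zero = analyse voxel).
#' @param tr_s repetition time in seconds; if `NULL`, taken from the NIfTI
#'   header pixdim.
#' @param n_discard leading volumes to drop (default 4).
#' @param subject_id identifier stored in the result.
#' @return A `subject_scan`: list with `subject_id`, `data` (voxels x time),
#'   `geometry`, `mask_index`, `tr_s`, `n_discarded`.
#' @export
read_volume4d <- function(path, mask, tr_s = NULL, n_discard = 4L,
                          subject_id = basename(path)) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D NIfTI, got ", length(d), "D")
  md <- dim(mask)
  if (!identical(as.integer(d[1:3]), as.integer(md))) {
    stop(sprintf("geometry mismatch: volume %s vs mask %s",
                 paste(d[1:3], collapse = "x"),
                 paste(md, collapse = "x")))
  }
  if (is.null(tr_s)) {
    pd <- attr(img, "pixdim")
    tr_s <- if (!is.null(pd) && length(pd) >= 4) pd[4] else 1
  }
  stopifnot(tr_s > 0)
  n_discard <- as.integer(n_discard)
  t_total <- d[4]
  if (t_total - n_discard < 10L) {
    stop("fewer than 10 volumes remain after discarding ", n_discard)
  }
  idx <- mask_to_index(mask)
  arr <- as.array(img)
  dim(arr) <- c(prod(d[1:3]), t_total)
  dat <- arr[idx, (n_discard + 1L):t_total, drop = FALSE]
  if (any(!is.finite(dat))) stop("non-finite values in volume after load")
  vs <- attr(img, "pixdim")[1:3]
  geom <- volume_geometry(d[1:3], vs, xform_affine(img))
  subject_scan(subject_id, dat, geom, idx, tr_s, n_discard)
}

xform_affine <- function(img) {
  aff <- try(structure(RNifti::xform(img), dimnames = NULL), silent = TRUE)
  if (inherits(aff, "try-error") || !identical(dim(aff), c(4L, 4L))) return(NULL)
  # RNifti xforms can flip axes; rebuild a size-consistent affine if the
  # column norms disagree with pixdim (keeps volume_geometry invariant).
  vs <- attr(img, "pixdim")[1:3]
  if (max(abs(sqrt(colSums(aff[1:3, 1:3]^2)) - vs)) > 1e-6) return(NULL)
  unclass(aff)
}

#' Construct a subject scan container
#'
#' @param subject_id string.
#' @param data voxels x time numeric matrix (masked).
#' @param geometry a `volume_geometry`.
#' @param mask_index in-mask linear indices (length = nrow(data)).
#' @param tr_s repetition time (s).
#' @param n_discarded leading volumes already removed.
#' @return `subject_scan` object.
#' @export
subject_scan <- function(subject_id, data, geometry, mask_index, tr_s,
                         n_discarded = 0L) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(mask_index), tr_s > 0, n_discarded >= 0)
  if (any(!is.finite(data))) stop("non-finite values in scan data")
  structure(list(subject_id = subject_id, data = data, geometry = geometry,
                 mask_index = as.integer(mask_index), tr_s = tr_s,
                 n_discarded = as.integer(n_discarded)),
            class = "subject_scan")
}

#' Write a masked voxels-by-time matrix as a 4D NIfTI volume
#'
#' Out-of-mask voxels are written as zero. Data are stored as float32, the
#' conventional on-disk precision for fMRI derivatives.
#'
#' @param matrix voxels x time numeric matrix.
#' @param mask_index in-mask linear indices.
#' @param geometry a `volume_geometry`.
#' @param path output file path (.nii or .nii.gz).
#' @param tr_s repetition time written to the header.
#' @return `path`, invisibly.
#' @export
write_volume4d <- function(matrix, mask_index, geometry, path, tr_s = 1) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(mask_index)) {
    stop(sprintf("matrix has %d rows but mask has %d voxels",
                 nrow(matrix), length(mask_index)))
  }
  shp <- geometry$shape
  t_n <- ncol(matrix)
  arr <- array(0, dim = c(prod(shp), t_n))
  arr[mask_index, ] <- matrix
  dim(arr) <- c(shp, t_n)
  img <- RNifti::asNifti(arr)
  attr(img, "pixdim") <- c(geometry$voxel_size_mm, tr_s)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a 3D NIfTI volume restricted to a mask
#'
#' @param path NIfTI file with a single 3D volume.
#' @param mask 3D mask array of the same grid.
#' @return numeric vector of in-mask values.
#' @export
read_volume3d <- function(path, mask) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L) stop("expected a 3D NIfTI")
  if (!identical(as.integer(d), as.integer(dim(mask)))) {
    stop(sprintf("geometry mismatch: volume %s vs mask %s",
                 paste(d, collapse = "x"), paste(dim(mask), collapse = "x")))
  }
  as.vector(img)[mask_to_index(mask)]
}

#' Read SPM-style realignment parameters
#'
#' Motion files follow the SPM `rp_*.txt` dialect: whitespace-separated, six
#' columns (x, y, z translations in mm; pitch, roll, yaw rotations stored in
#' radians). Rotations are converted to degrees on load, exactly once.
#'
#' @param path text file of realignment parameters.
#' @param subject_id identifier stored in the result.
#' @return A `motion_trace`: list with `subject_id` and `params`, a time x 6
#'   matrix (mm, mm, mm, deg, deg, deg).
#' @export
read_motion_params <- function(path, subject_id = basename(path)) {
  raw <- utils::read.table(path, header = FALSE)
  if (ncol(raw) != 6L) {
    stop("motion parameter file must have 6 columns, found ", ncol(raw))
  }
  params <- as.matrix(raw)
  if (any(!is.finite(params))) stop("non-finite motion parameters")
  params[, 4:6] <- params[, 4:6] * 180 / pi
  colnames(params) <- c("tx_mm", "ty_mm", "tz_mm",
                        "rx_deg", "ry_deg", "rz_deg")
  structure(list(subject_id = subject_id, params = params),
            class = "motion_trace")
}

#' Write realignment parameters in the SPM dialect
#'
#' Inverse of [read_motion_params()]: rotations are given in degrees and
#' written in radians.
#'
#' @param params time x 6 matrix (translations mm, rotations degrees).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motion_params <- function(params, path) {
  stopifnot(ncol(params) == 6L)
  out <- params
  out[, 4:6] <- out[, 4:6] * pi / 180
  utils::write.table(format(out, digits = 10, scientific = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Allowed categorical values in the clinical table.
.clinical_groups <- c("HC", "BD")
.clinical_genders <- c("F", "M")
.clinical_required <- c("subject_id", "group", "age", "gender", "ymrs", "bdi",
                        "hamd", "n_depressive", "n_manic", "onset_age",
                        "remission_years", "psychosis_history", "medication")

# Drug name -> medication class lookup (drugs used in the cohort generator).
.drug_class <- c(
  lithium = "mood_stabilizer", valproate = "mood_stabilizer",
  lamotrigine = "mood_stabilizer", carbamazepine = "mood_stabilizer",
  venlafaxine = "antidepressant", citalopram = "antidepressant",
  sertraline = "antidepressant", duloxetine = "antidepressant",
  clomipramine = "antidepressant", mirtazapine = "antidepressant",
  opipramol = "antidepressant",
  quetiapine = "antipsychotic", perazine = "antipsychotic",
  risperidone = "antipsychotic", olanzapine = "antipsychotic",
  aripiprazole = "antipsychotic")

#' Parse one medication cell into a medication record
#'
#' A cell is a semicolon-separated list of `drug:dose` entries. For
#' antidepressants and mood stabilizers the dose is a level 1-4 (or the words
#' `lowdose` / `highdose`, mapping to levels 2 and 4). For antipsychotics the
#' dose is `cpz0`, `cpz1` or `cpz2` — the chlorpromazine-equivalent code. An
#' empty cell or `"none"` means no medication.
#'
#' @param cell character scalar.
#' @return list of entries, each with `drug`, `class`, and `dose_level`
#'   (AD/MS) or `cpz_code` (AP).
#' @export
parse_medication <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell)) || trimws(cell) == "none") {
    return(list())
  }
  entries <- strsplit(trimws(cell), ";", fixed = TRUE)[[1]]
  lapply(entries, function(e) {
    parts <- strsplit(trimws(e), ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed medication entry: ", e)
    drug <- tolower(parts[1]); dose <- tolower(parts[2])
    if (!drug %in% names(.drug_class)) stop("unknown drug: ", drug)
    cls <- .drug_class[[drug]]
    if (cls == "antipsychotic") {
      if (!grepl("^cpz[0-2]$", dose)) {
        stop("antipsychotic dose must be cpz0/cpz1/cpz2, got: ", dose)
      }
      list(drug = drug, class = cls,
           cpz_code = as.integer(sub("cpz", "", dose)))
    } else {
      lvl <- switch(dose, lowdose = 2L, highdose = 4L,
                    suppressWarnings(as.integer(dose)))
      if (is.na(lvl) || lvl < 1L || lvl > 4L) {
        stop("dose level must be 1-4 (or lowdose/highdose), got: ", dose)
      }
      list(drug = drug, class = cls, dose_level = lvl)
    }
  })
}

#' Read the clinical table
#'
#' Expects a CSV with one row per subject and columns `subject_id`, `group`
#' (HC/BD), `age`, `gender` (F/M), `ymrs`, `bdi`, `hamd`, `n_depressive`,
#' `n_manic`, `onset_age`, `remission_years`, `psychosis_history` (0/1),
#' `medication` (see [parse_medication()]). Adds a derived `med_load` column
#' (see [medication_load()]).
#'
#' @param path CSV file.
#' @return data.frame with typed columns, parsed `medication` (list column)
#'   and derived `med_load`.
#' @export
read_clinical_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.clinical_required, names(tab))
  if (length(missing)) {
    stop("clinical table missing required columns: ",
         paste(missing, collapse = ", "))
  }
  bad_grp <- setdiff(unique(tab$group), .clinical_groups)
  if (length(bad_grp)) stop("unknown group label(s): ",
                            paste(bad_grp, collapse = ", "))
  bad_gen <- setdiff(unique(tab$gender), .clinical_genders)
  if (length(bad_gen)) stop("unknown gender label(s): ",
                            paste(bad_gen, collapse = ", "))
  tab$psychosis_history <- as.logical(tab$psychosis_history)
  tab$medication <- lapply(tab$medication, parse_medication)
  tab$med_load <- vapply(tab$medication, medication_load, numeric(1))
  tab
}
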