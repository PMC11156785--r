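#' Write a slice to disk as NIfTI volumes with a YAML sidecar
#'
#' The repetition stack is written as one H x W x N NIfTI volume, each ROI
#' mask and the truth image (when present) as separate volumes, and a YAML
#' sidecar records provenance (patient id, dropout log, optional phantom
#' configuration).
#'
#' @param slice A `phantom_slice` (or compatible list).
#' @param dir Output directory (created if needed).
#' @param basename File-name stem, e.g. `"p01_s01"`.
#' @param config Optional [phantom_config()] echoed into the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_slice <- function(slice, dir, basename, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(suffix) file.path(dir, paste0(basename, "_", suffix,
                                                ".nii.gz"))
  RNifti::writeNifti(slice$stack, pth("stack"))
  for (nm in names(slice$rois))
    RNifti::writeNifti(slice$rois[[nm]] * 1L, pth(paste0("mask_", nm)))
  if (!is.null(slice$truth)) RNifti::writeNifti(slice$truth, pth("truth"))
  meta <- list(basename = basename, patient_id = slice$patient_id,
               dropout_log = slice$dropout_log)
  if (!is.null(config)) meta$phantom_config <-
    lapply(unclass(config), function(v) if (is.null(v)) NA else v)
  sidecar <- file.path(dir, paste0(basename, ".yaml"))
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}

#' Read a slice back from NIfTI volumes
#'
#' Loads the stack and masks written by [write_slice()], validates that all
#' volumes share one grid, binarizes the masks, and computes the
#' trace-weighted reference when no reference volume is stored. A missing
#' lesion mask is tolerated: the slice loads with an all-`FALSE` lesion
#' mask and lesion-dependent scores flagged unavailable.
#'
#' @param dir Directory holding the volumes.
#' @param basename File-name stem used at write time.
#' @param dirs_per_rep Passed to [trace_reference()].
#' @return A list with `stack`, `rois`, `reference`, `truth` (or `NULL`),
#'   `patient_id`, `has_lesions`.
#' @export
read_slice <- function(dir, basename, dirs_per_rep = 3) {
  pth <- function(suffix) file.path(dir, paste0(basename, "_", suffix,
                                                ".nii.gz"))
  read_vol <- function(p) {
    if (!file.exists(p)) return(NULL)
    v <- tryCatch(RNifti::readNifti(p),
                  error = function(e) stop(sprintf(
                    "failed to read '%s': %s", p, conditionMessage(e)),
                    call. = FALSE))
    a <- as.array(v)
    attributes(a) <- list(dim = dim(a))
    a
  }
  stack <- read_vol(pth("stack"))
  if (is.null(stack)) stop(sprintf("missing stack volume for '%s'",
                                   basename), call. = FALSE)
  grid <- dim(stack)[1:2]
  get_mask <- function(nm, required = TRUE) {
    m <- read_vol(pth(paste0("mask_", nm)))
    if (is.null(m)) {
      if (required) stop(sprintf("missing required mask '%s'", nm),
                         call. = FALSE)
      return(matrix(FALSE, grid[1], grid[2]))
    }
    m <- matrix(m, grid[1], grid[2])
    if (!identical(dim(m), grid))
      stop(sprintf("mask '%s' is not on the stack grid", nm), call. = FALSE)
    m > 0.5
  }
  rois <- roi_set(left_lobe = get_mask("left_lobe"),
                  right_lobe = get_mask("right_lobe"),
                  vessels = get_mask("vessels"),
                  lesions = get_mask("lesions", required = FALSE),
                  background = get_mask("background"))
  truth <- read_vol(pth("truth"))
  if (!is.null(truth)) truth <- matrix(truth, grid[1], grid[2])
  reference <- read_vol(pth("reference"))
  reference <- if (is.null(reference)) trace_reference(stack, dirs_per_rep)
               else matrix(reference, grid[1], grid[2])
  meta_path <- file.path(dir, paste0(basename, ".yaml"))
  patient_id <- NA_integer_
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$patient_id)) patient_id <- meta$patient_id
  }
  list(stack = stack, rois = rois, reference = reference, truth = truth,
       patient_id = patient_id, has_lesions = any(rois$lesions))
}

#' Benchmark combination methods on a dataset
#'
#' Runs each requested method over every slice, scores against the
#' trace-weighted reference, and returns one row of mean normalized scores
#' and Qtotal per method — the comparison table the quality-score framework
#' is built for. An `identity` row (the reference scored against itself,
#' all ones) can be included as a sanity anchor, and a fitted [fit_pulsenet()]
#' model contributes a `deep_learning` row.
#'
#' @param dataset List of slices (`stack` + `rois`).
#' @param algorithms Named list: each element a list with `algorithm` and
#'   `params` as in [combine_stack()].
#' @param model Optional fitted `pulsenet`.
#' @param include_identity Prepend the identity row?
#' @param dirs_per_rep Passed to [trace_reference()].
#' @return Data frame with columns `method`, `pa_n`, `dc_n`, `vd_n`,
#'   `cnr_n`, `qtotal`, in deterministic order.
#' @export
run_benchmark <- function(dataset, algorithms = list(), model = NULL,
                          include_identity = FALSE, dirs_per_rep = 3) {
  rows <- list()
  if (include_identity) {
    refs <- lapply(dataset, function(sl) trace_reference(sl$stack,
                                                         dirs_per_rep))
    sc <- score_dataset(dataset, refs, dirs_per_rep)
    rows[["identity"]] <- sc$mean
  }
  for (nm in names(algorithms)) {
    a <- algorithms[[nm]]
    imgs <- lapply(dataset, function(sl)
      combine_stack(sl$stack, a$algorithm, a$params))
    rows[[nm]] <- score_dataset(dataset, imgs, dirs_per_rep)$mean
  }
  if (!is.null(model)) {
    imgs <- lapply(dataset, function(sl) predict(model, sl$stack))
    rows[["deep_learning"]] <- score_dataset(dataset, imgs,
                                             dirs_per_rep)$mean
  }
  if (length(rows) == 0) stop("nothing to benchmark", call. = FALSE)
  out <- data.frame(method = names(rows),
                    do.call(rbind, rows), row.names = NULL)
  out
}
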