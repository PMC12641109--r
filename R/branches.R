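#' Branch vocabulary
#'
#' The classifier consumes five feature branches per subject: one per MRI
#' modality (FLAIR, T1, T2, T1wCE) plus the delta branch computed from the
#' voxelwise T1wCE - T1 difference image. Branch order is fixed everywhere
#' (feature tables, model weights, attention vectors) so that serialized
#' artifacts interoperate.
#'
#' @return `mgmt_branches()` returns the five branch names in canonical
#'   order; `branch_feature_names()` returns the 400 column names of one
#'   branch (`<branch>_f000` .. `<branch>_f399`); `cohort_feature_names()`
#'   returns all 2000 feature column names in branch order.
#' @export
mgmt_branches <- function() {
  c("flair", "t1", "t2", "t1wce", "delta_t1")
}

#' @rdname mgmt_branches
#' @param branch one of `mgmt_branches()`
#' @param n_features features per branch (default 400)
#' @export
branch_feature_names <- function(branch, n_features = 400L) {
  branch <- match.arg(branch, mgmt_branches())
  sprintf("%s_f%03d", branch, seq_len(n_features) - 1L)
}

#' @rdname mgmt_branches
#' @export
cohort_feature_names <- function(n_features = 400L) {
  unlist(lapply(mgmt_branches(), branch_feature_names, n_features = n_features),
         use.names = FALSE)
}

#' Extract one branch of a cohort as a numeric matrix
#'
#' @param cohort a cohort tibble (see [generate_feature_cohort()])
#' @param branch branch name
#' @return an `n_subjects x n_features` matrix, rownames = subject ids
#' @export
cohort_branch_matrix <- function(cohort, branch) {
  branch <- match.arg(branch, mgmt_branches())
  cols <- grep(paste0("^", branch, "_f\\d+$"), names(cohort), value = TRUE)
  if (length(cols) == 0L) {
    stop("cohort has no feature columns for branch '", branch, "'")
  }
  m <- as.matrix(cohort[cols])
  rownames(m) <- cohort$subject_id
  m
}

#' Number of features per branch in a cohort
#' @param cohort a cohort tibble
#' @keywords internal
cohort_n_features <- function(cohort) {
  length(grep("^flair_f\\d+$", names(cohort)))
}

# derive a reproducible 32-bit substream seed from a parent seed
derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647
}
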