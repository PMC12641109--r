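# extractor registry -----------------------------------------------------

.extractors <- new.env(parent = emptyenv())

#' Feature extractor registry
#'
#' An extractor is a pure function `clip -> 400 finite numerics`. The
#' deterministic `"stub"` extractor is registered at load time; adapters
#' wrapping pre-trained video networks (I3D, SlowFast, IRCSN, ViViT) can be
#' registered under their own names behind the identical contract. Any
#' channel replication or frame subsampling a pre-trained backbone needs is
#' the adapter's responsibility; the core contract fixes only the output
#' dimension.
#'
#' @param name extractor id
#' @param fn function taking a `video_clip` and returning 400 numerics
#' @export
register_extractor <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .extractors)
  invisible(name)
}

#' @rdname register_extractor
#' @export
list_extractors <- function() sort(ls(.extractors))

get_extractor <- function(extractor) {
  if (is.function(extractor)) return(extractor)
  if (!exists(extractor, envir = .extractors, inherits = FALSE)) {
    stop("unknown extractor '", extractor, "'")
  }
  get(extractor, envir = .extractors)
}

#' Extract a 400-dimensional deep-feature vector from a clip
#'
#' Dispatches to a registered extractor and enforces the dimension
#' contract: exactly 400 finite values per clip, purely a function of clip
#' content.
#'
#' @param clip a `video_clip` (see [volume_to_video()])
#' @param extractor registry name or extractor function
#' @return numeric length-400 vector with attribute `extractor_id`
#' @export
extract_features <- function(clip, extractor = "stub") {
  stopifnot(inherits(clip, "video_clip"))
  fn <- get_extractor(extractor)
  v <- as.numeric(fn(clip))
  if (length(v) != 400L || !all(is.finite(v))) {
    stop("dimension contract violated: extractor must emit 400 finite values")
  }
  attr(v, "extractor_id") <-
    if (is.character(extractor)) extractor else "custom"
  v
}

# fixed projection of the stub extractor, generated once from a pinned seed
stub_projection <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- withr::with_seed(392871L, {
        list(P = matrix(stats::rnorm(400L * 30L, sd = 0.5), 400L, 30L),
             bias = stats::rnorm(400L))
      })
    }
    cache
  }
})

#' Deterministic stub feature extractor
#'
#' A download-free stand-in for pre-trained video networks: the clip is cut
#' into 10 temporal blocks of 15 frames; per block the mean intensity,
#' intensity variance and gradient energy (mean squared in-plane forward
#' difference) are computed on the 0-1 rescaled frames, and the resulting
#' 30-moment vector is projected through a fixed seeded random 400 x 30
#' matrix plus bias. Distinct clips map to distinct vectors and the
#' all-zero clip maps exactly to the bias vector.
#'
#' @param clip a `video_clip`
#' @return numeric length-400
#' @export
stub_extract <- function(clip) {
  stopifnot(inherits(clip, "video_clip"))
  fr <- clip$frames / 255
  nb <- 10L
  per <- dim(fr)[1] / nb
  moments <- numeric(3L * nb)
  for (b in seq_len(nb)) {
    blk <- fr[(b - 1L) * per + seq_len(per), , , drop = FALSE]
    grad <- mean((blk[, -1, , drop = FALSE] -
                    blk[, -dim(blk)[2], , drop = FALSE])^2) +
            mean((blk[, , -1, drop = FALSE] -
                    blk[, , -dim(blk)[3], drop = FALSE])^2)
    moments[3L * (b - 1L) + 1:3] <-
      c(mean(blk), stats::var(as.vector(blk)), grad)
  }
  pr <- stub_projection()
  as.numeric(pr$P %*% moments + pr$bias)
}

#' Assemble the five branch clips of a subject into a feature-set row
#'
#' Requires exactly the five branches (`flair`, `t1`, `t2`, `t1wce`,
#' `delta_t1`); input order is irrelevant because assembly sorts into
#' canonical branch order. Missing-modality inference is handled by the
#' model, not here.
#'
#' @param clips named list of the 5 `video_clip`s
#' @param extractor extractor id or function
#' @param subject_id subject identifier
#' @param label 0/1 MGMT status (1 = methylated) or `NA`
#' @return one-row cohort tibble (`subject_id`, `label`, 2000 feature
#'   columns)
#' @export
assemble_subject <- function(clips, extractor = "stub",
                             subject_id = "S0001", label = NA_integer_) {
  br <- mgmt_branches()
  if (anyDuplicated(names(clips)) > 0) stop("duplicate branch in clips")
  if (!setequal(names(clips), br)) {
    stop("clips must contain exactly the branches: ",
         paste(br, collapse = ", "))
  }
  if (!is.na(label) && !label %in% c(0L, 1L)) stop("label must be 0/1 or NA")
  feats <- unlist(lapply(br, function(b) {
    v <- extract_features(clips[[b]], extractor)
    stats::setNames(v, branch_feature_names(b, length(v)))
  }))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, label = as.integer(label)),
    tibble::as_tibble(as.list(feats)))
  attr(out, "extractor_id") <-
    if (is.character(extractor)) extractor else "custom"
  out
}

# cohort tibble validation shared by I/O and models
validate_cohort <- function(cohort, require_label = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (!"subject_id" %in% names(cohort)) stop("cohort lacks subject_id column")
  if (anyDuplicated(cohort$subject_id) > 0) stop("duplicate subject_ids")
  nf <- cohort_n_features(cohort)
  if (nf == 0L) stop("cohort has no feature columns")
  for (b in mgmt_branches()) {
    cols <- branch_feature_names(b, nf)
    if (!all(cols %in% names(cohort))) {
      stop("cohort branch '", b, "' is incomplete")
    }
  }
  if (require_label) {
    if (!"label" %in% names(cohort) || anyNA(cohort$label)) {
      stop("cohort labels are required but missing")
    }
    if (!all(cohort$label %in% c(0L, 1L))) stop("labels must be 0/1")
  }
  invisible(cohort)
}

#' Feature-table I/O
#'
#' Lossless CSV round-trip of a cohort: header
#' `subject_id,label,<branch>_f000..f399`, with the extractor id and cohort
#' name carried in leading `#` comment lines. Reading validates shapes,
#' rejects non-finite cells with a row/column report, and flags a missing
#' label column (attribute `labels_missing`) rather than failing.
#'
#' @param cohort cohort tibble
#' @param path CSV path
#' @export
write_feature_table <- function(cohort, path) {
  validate_cohort(cohort)
  ex <- attr(cohort, "extractor_id") %||% "unknown"
  nm <- attr(cohort, "cohort_name") %||% "cohort"
  writeLines(c(paste0("# extractor_id: ", ex),
               paste0("# cohort_name: ", nm)), path)
  readr::write_csv(cohort, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @return `read_feature_table()` returns the cohort tibble with
#'   `extractor_id` / `cohort_name` attributes restored
#' @export
read_feature_table <- function(path) {
  head_lines <- readLines(path, n = 5L)
  meta_of <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), head_lines, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1]) else NULL
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  labels_missing <- !"label" %in% names(out)
  if (labels_missing) {
    out <- dplyr::mutate(out, label = NA_integer_, .after = "subject_id")
  } else {
    out$label <- as.integer(out$label)
  }
  feat_cols <- setdiff(names(out), c("subject_id", "label"))
  bad <- which(!as.matrix(dplyr::summarise(
    out, dplyr::across(dplyr::all_of(feat_cols), ~ all(is.finite(.x))))))
  if (length(bad) > 0) {
    col <- feat_cols[bad[1]]
    row <- which(!is.finite(out[[col]]))[1]
    stop("non-finite feature cell at row ", row, ", column '", col, "'")
  }
  validate_cohort(out)
  attr(out, "extractor_id") <- meta_of("extractor_id") %||% "unknown"
  attr(out, "cohort_name") <- meta_of("cohort_name") %||% "cohort"
  attr(out, "labels_missing") <- labels_missing
  out
}

#' Featurize a preprocessed subject end to end
#'
#' Convenience wrapper: phantom/real volumes + mask -> five clips ->
#' one-row cohort tibble.
#'
#' @inheritParams preprocess_subject
#' @inheritParams assemble_subject
#' @export
featurize_subject <- function(volumes, mask, extractor = "stub",
                              subject_id = "S0001", label = NA_integer_) {
  prep <- preprocess_subject(volumes, mask)
  assemble_subject(prep$clips, extractor, subject_id, label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
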