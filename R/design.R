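# Between-image relatedness matrices K for the supported study designs.

.new_kinship <- function(K, design, ids = NULL) {
  K <- as.matrix(K)
  dimnames(K) <- if (is.null(ids)) NULL else list(ids, ids)
  attr(K, "design") <- design
  K
}

.check_psd <- function(K, tol = 1e-8) {
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  nrm <- max(abs(ev))
  if (min(ev) < -tol * max(nrm, 1))
    stop("relatedness matrix is not positive semidefinite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  invisible(ev)
}

#' Test-retest relatedness matrix
#'
#' K[i, i*] = 1 if images i and i* come from the same subject and 0 otherwise
#' (so the diagonal is 1). Replacing K by K - I shifts every score statistic
#' by a permutation-invariant constant and leaves all standardized statistics
#' unchanged, so the literal same-subject rule is kept.
#'
#' @param subject_ids length-N vector of subject labels, one per image, in
#'   the row order of the data matrix.
#' @return an N x N relatedness matrix with attribute `design = "test_retest"`.
#' @export
kinship_test_retest <- function(subject_ids) {
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) < 2L) stop("need at least two images")
  K <- (outer(subject_ids, subject_ids, "==")) * 1
  if (max(table(subject_ids)) < 2L)
    warning("every subject has a single image: the variance-component ",
            "statistic has no between-image signal to detect")
  .new_kinship(K, "test_retest", subject_ids)
}

#' Twin-design relatedness matrix
#'
#' Within a pair the off-diagonal coefficient is 1 for monozygotic (MZ) twins
#' and 0.5 for dizygotic (DZ) twins, reflecting expected additive genetic
#' sharing; images from different pairs are unrelated and the diagonal is 1.
#'
#' @param pair_ids length-N vector of pair labels; each label must appear
#'   exactly twice.
#' @param zygosity zygosity codes `"MZ"`/`"DZ"`, either length N (one per
#'   image, consistent within pair) or one per pair named by pair label.
#' @return an N x N relatedness matrix with attribute `design = "twin"`.
#' @export
kinship_twins <- function(pair_ids, zygosity) {
  pair_ids <- as.character(pair_ids)
  N <- length(pair_ids)
  tab <- table(pair_ids)
  if (any(tab != 2L))
    stop("each pair id must appear exactly twice; offending pair(s): ",
         paste(names(tab)[tab != 2L], collapse = ", "))
  zygosity <- toupper(as.character(zygosity))
  if (length(zygosity) == N) {
    per_pair <- tapply(zygosity, pair_ids, unique)
    if (any(lengths(per_pair) != 1L))
      stop("zygosity codes disagree within a pair")
    zy <- vapply(per_pair, identity, character(1))
  } else if (!is.null(names(zygosity)) &&
             setequal(names(zygosity), names(tab))) {
    zy <- zygosity[names(tab)]
  } else {
    stop("`zygosity` must have one code per image or one named code per pair")
  }
  if (!all(zy %in% c("MZ", "DZ")))
    stop("unknown zygosity code(s): ",
         paste(setdiff(zy, c("MZ", "DZ")), collapse = ", "))
  coef <- unname(c(MZ = 1, DZ = 0.5)[zy])
  names(coef) <- names(tab)
  same <- outer(pair_ids, pair_ids, "==")
  K <- same * coef[pair_ids]
  diag(K) <- 1
  .new_kinship(K, "twin", pair_ids)
}

#' Load a custom relatedness matrix
#'
#' Reads a square delimited matrix (e.g., a genetic relationship matrix for a
#' pedigree study), symmetrizes it as (K + K')/2, and validates positive
#' semidefiniteness.
#'
#' @param path path to a delimited square numeric table; an optional header
#'   row/column of image ids is matched against the data matrix order by the
#'   caller.
#' @param tol relative PSD tolerance on the smallest eigenvalue.
#' @return the validated relatedness matrix with attribute `design = "custom"`.
#' @export
load_custom_kinship <- function(path, tol = 1e-8) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  ids <- NULL
  if (ncol(dt) && !is.numeric(dt[[1L]])) {
    ids <- as.character(dt[[1L]])
    dt <- dt[, -1L, drop = FALSE]
  }
  K <- as.matrix(dt)
  if (!is.numeric(K)) stop("relatedness matrix contains non-numeric entries")
  if (!.is_square(K))
    stop("relatedness matrix must be square, got ", nrow(K), " x ", ncol(K))
  K <- (K + t(K)) / 2
  .check_psd(K, tol)
  .new_kinship(K, "custom", ids)
}

#' Relatedness matrix from a study-design table
#'
#' Dispatches on the columns of a design table: `subject_id` selects the
#' test-retest design, `pair_id` + `zygosity` the twin design.
#'
#' @param design data frame with column `image_id` plus either `subject_id`
#'   or `pair_id` and `zygosity`.
#' @return an N x N relatedness matrix.
#' @export
kinship_from_design <- function(design) {
  design <- as.data.frame(design)
  if ("subject_id" %in% names(design))
    return(kinship_test_retest(design$subject_id))
  if (all(c("pair_id", "zygosity") %in% names(design)))
    return(kinship_twins(design$pair_id, design$zygosity))
  stop("design table needs either a `subject_id` column or ",
       "`pair_id` + `zygosity` columns")
}
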