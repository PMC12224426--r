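# Delimited-text readers and writers. Comma/tab separated files are the
# canonical interchange format; the separator is autodetected by fread.

#' Read an images-by-vertices data matrix
#'
#' One row per image; a non-numeric first column is taken as image ids. When
#' `ids` is supplied, rows are matched and, if needed, explicitly reordered
#' to that order (with a message).
#'
#' @param path delimited file.
#' @param ids optional character vector giving the required image order
#'   (e.g., from the design table).
#' @return numeric matrix with image ids as row names when available.
#' @export
read_data_matrix <- function(path, ids = NULL) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  rn <- NULL
  if (ncol(dt) && !is.numeric(dt[[1L]])) {
    rn <- as.character(dt[[1L]])
    dt <- dt[, -1L, drop = FALSE]
  }
  num <- vapply(dt, is.numeric, logical(1L))
  if (!all(num))
    stop("non-numeric data column(s): ",
         paste(names(dt)[!num], collapse = ", "))
  Y <- as.matrix(dt)
  if (anyNA(Y)) {
    w <- which(is.na(Y), arr.ind = TRUE)[1L, ]
    stop("missing value at row ", w[1L], ", column ", w[2L])
  }
  rownames(Y) <- rn
  colnames(Y) <- NULL
  if (!is.null(ids)) {
    if (is.null(rn)) {
      if (nrow(Y) != length(ids))
        stop("data matrix has ", nrow(Y), " rows but the design lists ",
             length(ids), " images")
    } else {
      idx <- match(ids, rn)
      if (anyNA(idx))
        stop("image id(s) missing from the data matrix: ",
             paste(ids[is.na(idx)], collapse = ", "))
      if (!identical(idx, seq_along(ids))) {
        message("reordering data rows to match the design table")
        Y <- Y[idx, , drop = FALSE]
      }
    }
  }
  Y
}

#' Read a study-design table
#'
#' Expects a column `image_id` plus either `subject_id` (test-retest) or
#' `pair_id` and `zygosity` (twin design).
#'
#' @param path delimited file.
#' @return data frame.
#' @export
read_design_table <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE,
                         colClasses = "character")
  if (!"image_id" %in% names(d)) stop("design table needs an `image_id` column")
  if (!("subject_id" %in% names(d) ||
        all(c("pair_id", "zygosity") %in% names(d))))
    stop("design table needs `subject_id` or `pair_id` + `zygosity` columns")
  d
}

#' Load a mesh from delimited coordinate and face tables
#'
#' Coordinates are one `x y [z]` row per vertex; faces are one `i j k` row
#' per triangle. Face files default to 0-based indexing; set
#' `index_base = 1` for 1-based files.
#'
#' @param vertex_table path to the coordinate table (no header required).
#' @param face_table path to the face table.
#' @param mask optional path to a one-column 0/1 mask file, or a logical
#'   vector.
#' @param index_base 0 or 1; the face indexing convention of the file.
#' @return a `cleanv_surface` (distances unset; see [geodesic_distances()]).
#' @export
load_mesh <- function(vertex_table, face_table, mask = NULL,
                      index_base = 0L) {
  if (!index_base %in% c(0L, 1L)) stop("`index_base` must be 0 or 1")
  coords <- as.matrix(data.table::fread(vertex_table, header = FALSE))
  faces <- as.matrix(data.table::fread(face_table, header = FALSE))
  if (!is.numeric(faces)) stop("face table must be numeric")
  faces <- faces + (1L - as.integer(index_base))
  if (is.character(mask) && length(mask) == 1L)
    mask <- data.table::fread(mask, header = FALSE)[[1L]] != 0
  surface_geometry(coords, faces, mask = mask)
}

#' Read a precomputed distance matrix
#'
#' @param path delimited square numeric matrix (optional id header
#'   row/column).
#' @return numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) && !is.numeric(dt[[1L]])) dt <- dt[, -1L, drop = FALSE]
  D <- as.matrix(dt)
  if (!.is_square(D)) stop("distance matrix must be square")
  dimnames(D) <- NULL
  D
}

#' Write analysis results
#'
#' Writes (a) a per-vertex table `vertex_stats.csv` with columns `vertex`,
#' `U`, `Tv`, `argmax_radius`, `significant` (0/1), and `Tv_thresholded`
#' (Tv shrunk to zero below the threshold, the convention used for surface
#' maps), and (b) a JSON run summary `summary.json` with the global
#' statistic, threshold, p-value, fitted noise parameters, and config echo.
#'
#' @param result a `cleanv_result`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "cleanv_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  V <- result$config$V
  sig <- integer(V); sig[result$significant] <- 1L
  tab <- data.frame(
    vertex = seq_len(V),
    U = result$U,
    Tv = result$Tv,
    argmax_radius = result$argmax_radius,
    significant = sig,
    Tv_thresholded = ifelse(!is.na(result$Tv) & result$Tv > result$t_alpha,
                            result$Tv, 0))
  vpath <- file.path(outdir, "vertex_stats.csv")
  data.table::fwrite(tab, vpath)
  summ <- list(
    T = result$T, T_vertex = result$T_vertex, t_alpha = result$t_alpha,
    p_global = result$p_global,
    n_significant = length(result$significant),
    sigma2 = if (is.null(result$params)) NULL else result$params$sigma2,
    tau2 = if (is.null(result$params)) NULL else result$params$tau2,
    phi = if (is.null(result$params)) NULL else result$params$phi,
    config = result$config)
  spath <- file.path(outdir, "summary.json")
  jsonlite::write_json(summ, spath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(vertex_stats = vpath, summary = spath))
}

#' Write a simulated dataset in the analysis input formats
#'
#' Writes `data.csv` (image id + vertex columns), `design.csv`,
#' `coords.csv`/`faces.csv` (0-based faces), and `mask.csv`, so a simulated
#' dataset round-trips through the same readers the analysis uses.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory.
#' @param scenario the generating `cleanv_scenario` (used for the design
#'   columns).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, outdir, scenario) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  N <- nrow(sim$Y)
  ids <- paste0("img", seq_len(N))
  dat <- data.frame(image_id = ids, sim$Y, check.names = FALSE)
  names(dat)[-1L] <- paste0("v", seq_len(ncol(sim$Y)))
  data.table::fwrite(dat, file.path(outdir, "data.csv"))
  unit <- rep(seq_len(N / 2L), each = 2L)
  design <- if (scenario$mode == "twin") {
    zy <- attr(sim$K, "design")
    data.frame(image_id = ids, pair_id = paste0("p", unit),
               zygosity = ifelse(sim$K[cbind(seq_len(N),
                                             ifelse(seq_len(N) %% 2L == 1L,
                                                    seq_len(N) + 1L,
                                                    seq_len(N) - 1L))] == 1,
                                 "MZ", "DZ"))
  } else {
    data.frame(image_id = ids, subject_id = paste0("s", unit))
  }
  data.table::fwrite(design, file.path(outdir, "design.csv"))
  geom <- sim$geometry
  data.table::fwrite(as.data.frame(geom$coords),
                     file.path(outdir, "coords.csv"), col.names = FALSE)
  data.table::fwrite(as.data.frame(geom$faces - 1L),
                     file.path(outdir, "faces.csv"), col.names = FALSE)
  data.table::fwrite(data.frame(as.integer(geom$mask)),
                     file.path(outdir, "mask.csv"), col.names = FALSE)
  invisible(file.path(outdir, c("data.csv", "design.csv", "coords.csv",
                                "faces.csv", "mask.csv")))
}
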