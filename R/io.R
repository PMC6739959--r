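#' Read a TPS landmark file
#'
#' Parses the tpsDig dialect: each record starts with \code{LM=<k>}, followed
#' by k whitespace-separated coordinate lines and optional \code{ID=},
#' \code{IMAGE=} and \code{SCALE=} lines. Point order within a record is the
#' homology order and is preserved exactly.
#'
#' @param path path to a TPS file.
#' @param applyScale if \code{TRUE}, multiply coordinates by the record's
#'   SCALE factor; by default the factor is stored in the result and the raw
#'   digitized coordinates are kept.
#' @return a \linkS4class{LandmarkSet}; all records must share the same
#'   landmark count.
#' @seealso [writeTPS()] for the exact-round-trip writer.
#' @export
readTPS <- function(path, applyScale = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  recno <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("TPS parse error at line ", i, ": expected LM= record header")
    recno <- recno + 1L
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("TPS parse error in record ", recno, ": bad LM count at line ", i)
    i <- i + 1L
    pts <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      if (i > length(lines) || grepl("^[A-Za-z]+\\s*=", trimws(lines[i])))
        stop("TPS parse error in record ", recno,
             ": LM=", k, " but fewer coordinate lines found")
      xy <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                 "\\s+")[[1]]))
      if (length(xy) != 2L || any(is.na(xy)))
        stop("TPS parse error: non-numeric coordinate at line ", i)
      pts[j, ] <- xy
      i <- i + 1L
    }
    id <- NULL; scl <- NA_real_; meta <- list()
    while (i <= length(lines) && nzchar(trimws(lines[i])) &&
           grepl("^[A-Za-z]+\\s*=", trimws(lines[i]))) {
      ln <- trimws(lines[i])
      key <- toupper(sub("\\s*=.*$", "", ln))
      val <- sub("^[A-Za-z]+\\s*=\\s*", "", ln)
      if (key == "LM") break
      if (key == "ID") id <- val
      else if (key == "SCALE") scl <- as.numeric(val)
      else meta[[key]] <- val
      i <- i + 1L
    }
    if (is.null(id)) id <- paste0("record", recno)
    recs[[recno]] <- list(pts = pts, id = id, scale = scl, meta = meta)
  }
  if (!length(recs)) stop("no TPS records found in ", path)
  ks <- vapply(recs, function(r) nrow(r$pts), integer(1))
  if (length(unique(ks)) != 1L)
    stop("records have differing landmark counts: ",
         paste(unique(ks), collapse = ", "))
  a <- array(0, dim = c(ks[1], 2L, length(recs)))
  for (j in seq_along(recs)) {
    p <- recs[[j]]$pts
    if (applyScale && !is.na(recs[[j]]$scale)) p <- p * recs[[j]]$scale
    a[, , j] <- p
  }
  scales <- vapply(recs, function(r) r$scale, numeric(1))
  if (all(is.na(scales))) scales <- numeric(0) else scales[is.na(scales)] <- 1
  landmarkSet(a, ids = vapply(recs, function(r) r$id, character(1)),
              scales = scales,
              metadata = list(records = lapply(recs, `[[`, "meta")))
}

#' Write a TPS landmark file
#'
#' Emits the dialect read by [readTPS()]; coordinates are written at full
#' double precision so a write/read round trip is bit-exact.
#'
#' @param x a \linkS4class{LandmarkSet} (may hold zero specimens, giving an
#'   empty file).
#' @param path output path.
#' @export
writeTPS <- function(x, path) {
  stopifnot(is(x, "LandmarkSet"))
  n <- nSpecimens(x)
  out <- character(0)
  ids <- specimenIDs(x)
  for (i in seq_len(n)) {
    m <- x@coords[, , i]
    out <- c(out, paste0("LM=", nrow(m)),
             sprintf("%.17g %.17g", m[, 1], m[, 2]),
             paste0("ID=", ids[i]))
    if (length(x@scales)) out <- c(out, sprintf("SCALE=%.17g", x@scales[i]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read/write wide-format coordinate CSV
#'
#' One row per specimen with columns \code{id, x1, y1, ..., xk, yk}; header
#' required. Round trips are bit-exact.
#'
#' @param path file path.
#' @return for the reader, a \linkS4class{LandmarkSet}.
#' @export
readCoordsCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"id" %in% names(df)) stop("coordinate CSV must have an 'id' column")
  xy <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  if (ncol(xy) %% 2L != 0L) stop("odd number of coordinate columns")
  k <- ncol(xy) / 2L
  a <- array(0, dim = c(k, 2L, nrow(df)))
  for (i in seq_len(nrow(df)))
    a[, , i] <- matrix(xy[i, ], ncol = 2, byrow = TRUE)
  landmarkSet(a, ids = as.character(df$id))
}

#' @rdname readCoordsCSV
#' @param x a \linkS4class{LandmarkSet}.
#' @export
writeCoordsCSV <- function(x, path) {
  stopifnot(is(x, "LandmarkSet"))
  k <- nLandmarks(x)
  n <- nSpecimens(x)
  m <- matrix(NA_real_, n, 2 * k)
  for (i in seq_len(n)) m[i, ] <- as.vector(t(x@coords[, , i]))
  colnames(m) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))
  df <- data.frame(id = specimenIDs(x), m, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a rooted Newick tree
#'
#' Wraps \code{ape::read.tree} with the checks the comparative layer relies
#' on: one rooted tree, unique tip labels, branch lengths present and
#' non-negative. Zero-length terminal branches are permitted but flagged with
#' a warning (they make the Brownian covariance singular and are perturbed
#' downstream).
#'
#' @param path path to a Newick file (or a Newick string via \code{text}).
#' @param text optional Newick string, used instead of \code{path}.
#' @return an \code{ape} \code{phylo} object.
#' @export
readNewick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text)
        else ape::read.tree(path)
  if (is.null(tr)) stop("Newick parse error (unbalanced parentheses?)")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip names in tree")
  if (is.null(tr$edge.length)) stop("tree must have branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  term <- tr$edge[, 2] <= length(tr$tip.label)
  if (any(tr$edge.length[term] == 0))
    warning("zero-length terminal branches present")
  tr
}

#' Read and validate a semilandmark slider table
#'
#' A slider table has columns \code{before, slider, after}: 1-based indices
#' into the template's point order, the \code{slider} point sliding along the
#' chord from \code{before} to \code{after}.
#'
#' @param path CSV path with header \code{before,slider,after}.
#' @return a validated data.frame.
#' @export
readSliderTable <- function(path) {
  df <- utils::read.csv(path)
  validateSliderTable(df)
}

#' @rdname readSliderTable
#' @param sliders a data.frame with columns \code{before, slider, after}.
#' @param k optional landmark count to range-check against.
#' @export
validateSliderTable <- function(sliders, k = NULL) {
  need <- c("before", "slider", "after")
  if (!all(need %in% names(sliders)))
    stop("slider table needs columns before, slider, after")
  sliders <- sliders[, need]
  for (i in seq_len(nrow(sliders))) {
    r <- unlist(sliders[i, ])
    if (anyDuplicated(r)) stop("slider row ", i, ": indices must be distinct")
  }
  if (anyDuplicated(sliders$slider))
    stop("each slider index may appear at most once")
  if (!is.null(k) && any(unlist(sliders) < 1 | unlist(sliders) > k))
    stop("slider indices out of range 1..", k)
  sliders
}

#' @rdname readSliderTable
#' @export
writeSliderTable <- function(sliders, path) {
  utils::write.csv(validateSliderTable(sliders), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a specimen metadata table
#'
#' Columns \code{specimen_id, species, group, structure}; \code{group} is one
#' of \code{subterranean} / \code{non-subterranean} and \code{structure} one
#' of \code{humerus} / \code{mandible}. Each specimen id appears at most once
#' per structure and every species maps to exactly one group.
#'
#' @param path CSV path.
#' @return a validated data.frame.
#' @export
readSpecimenTable <- function(path) {
  validateSpecimenTable(utils::read.csv(path))
}

#' @rdname readSpecimenTable
#' @param df a data.frame with the four required columns.
#' @export
validateSpecimenTable <- function(df) {
  need <- c("specimen_id", "species", "group", "structure")
  if (!all(need %in% names(df)))
    stop("specimen table needs columns ", paste(need, collapse = ", "))
  if (!all(df$group %in% c("subterranean", "non-subterranean")))
    stop("group must be 'subterranean' or 'non-subterranean'")
  for (s in unique(df$structure)) {
    ids <- df$specimen_id[df$structure == s]
    if (anyDuplicated(ids))
      stop("duplicate specimen ids within structure ", s)
  }
  gm <- unique(df[, c("species", "group")])
  if (anyDuplicated(gm$species))
    stop("a species maps to more than one group")
  if ("cs" %in% names(df) && (!is.numeric(df$cs) ||
                              any(!is.finite(df$cs) | df$cs <= 0)))
    stop("cs must be positive and finite")
  df
}
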