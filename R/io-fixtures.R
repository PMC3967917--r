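## Plain-text readers/writers and the synthetic pseudo-brain fixture.
## External node ids are 0-based in all files (connectome tools vary;
## this package is explicit about it); internally igraph is 1-based.

#' Read a graph from an edge list or dense adjacency file
#'
#' Edge lists are two tab-separated integer columns of 0-based node ids,
#' with optional `#` comment lines. Dense adjacency files are N lines of N
#' whitespace-separated entries; non-0/1 entries are binarized with a
#' warning. Duplicate pairs and self-loops are dropped with a warning.
#'
#' @param path Input file path.
#' @param format `"edgelist"` or `"dense"`.
#' @param n_nodes Optional node count for edge lists whose highest-index
#'   nodes are isolated.
#' @return An igraph object.
#' @export
read_network <- function(path, format = c("edgelist", "dense"),
                         n_nodes = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (format == "edgelist") {
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- which(lengths(parts) != 2)
    if (length(bad) > 0)
      stop(sprintf("parse error at line %d: expected 2 columns",
                   lineno[bad[1]]), call. = FALSE)
    flat <- suppressWarnings(as.numeric(unlist(parts)))
    if (anyNA(flat) || any(flat != floor(flat)) || any(flat < 0))
      stop(sprintf("parse error at line %d: non-integer node id",
                   lineno[which(is.na(flat) | flat != floor(flat) |
                                  flat < 0)[1] %/% 2 + 1]), call. = FALSE)
    e <- matrix(as.integer(flat), ncol = 2, byrow = TRUE) + 1L
    n <- max(e, n_nodes %||% 0)
    if (!is.null(n_nodes) && max(e) > n_nodes)
      stop("node id out of range for `n_nodes`", call. = FALSE)
    loops <- e[, 1] == e[, 2]
    if (any(loops)) {
      warning(sprintf("%d self-loop(s) dropped", sum(loops)))
      e <- e[!loops, , drop = FALSE]
    }
    idx <- pair_to_index(e[, 1], e[, 2])
    if (anyDuplicated(idx)) {
      warning(sprintf("%d duplicate edge(s) dropped", sum(duplicated(idx))))
      e <- e[!duplicated(idx), , drop = FALSE]
    }
    edges_to_graph(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])), n)
  } else {
    rows <- strsplit(trimws(lines), "\\s+")
    n <- length(rows)
    if (any(lengths(rows) != n))
      stop(sprintf("parse error at line %d: expected %d columns",
                   lineno[which(lengths(rows) != n)[1]], n), call. = FALSE)
    w <- matrix(as.numeric(unlist(rows)), n, n, byrow = TRUE)
    if (anyNA(w)) stop("parse error: non-numeric matrix entry",
                       call. = FALSE)
    if (any(!w %in% c(0, 1)))
      warning("non-0/1 entries binarized")
    binarize(pmax(w, t(w)))
  }
}

#' Write a graph to an edge list or dense adjacency file
#'
#' @param g An undirected igraph object.
#' @param path Output file path.
#' @param format `"edgelist"` (0-based tab-separated pairs) or `"dense"`.
#' @export
write_network <- function(g, path, format = c("edgelist", "dense")) {
  format <- match.arg(format)
  check_graph(g)
  if (format == "edgelist") {
    e <- edge_ends(g) - 1L
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    writeLines(c(sprintf("# nodes: %d", igraph::vcount(g)),
                 sprintf("%d\t%d", pmin(e[, 1], e[, 2]),
                         pmax(e[, 1], e[, 2]))), path)
  } else {
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    writeLines(apply(a, 1, paste, collapse = " "), path)
  }
  invisible(path)
}

#' Read and write node coordinates
#'
#' Coordinates files are tab-separated with columns id (0-based), x, y, z
#' in millimetres and an optional fifth hemisphere column (`L`/`R`); no
#' header, `#` comments allowed.
#'
#' @param path File path.
#' @return For `read_coordinates()`: an n x 3 numeric matrix ordered by
#'   id, with a `hemisphere` attribute when the column is present.
#' @export
read_coordinates <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!ncol(df) %in% c(4, 5))
    stop("coordinates file must have 4 or 5 tab-separated columns",
         call. = FALSE)
  ord <- order(df[[1]])
  df <- df[ord, ]
  if (!identical(as.integer(df[[1]]), seq_len(nrow(df)) - 1L))
    stop("node ids must be contiguous 0-based integers", call. = FALSE)
  coords <- as.matrix(df[, 2:4])
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  if (ncol(df) == 5) attr(coords, "hemisphere") <- as.character(df[[5]])
  coords
}

#' @rdname read_coordinates
#' @param coords n x 3 coordinate matrix, optionally with a `hemisphere`
#'   attribute.
#' @export
write_coordinates <- function(coords, path) {
  check_coords(coords)
  df <- data.frame(id = seq_len(nrow(coords)) - 1L, coords)
  hemi <- attr(coords, "hemisphere")
  if (!is.null(hemi)) df$hemisphere <- hemi
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Synthetic pseudo-brain fixture
#'
#' Emulates a bilaterally embedded parcellation at configurable scale: `n/2`
#' coordinates are sampled per hemisphere on jittered spherical shells,
#' exactly mirrored across the midline (x -> -x), and a network is
#' generated on them by a named embedded model with recorded parameters.
#' The result is entirely synthetic -- no empirical brain data is involved
#' -- but exhibits hemisphere labels, bilateral symmetry, and a realistic
#' spread of inter-node distances, which is what embedded null models
#' need from an embedding. The `truth` field records everything required
#' to regenerate the fixture bit-identically.
#'
#' @param n Even number of nodes.
#' @param m Number of edges.
#' @param model Embedded model code: `"rg"`, `"mw"`, `"dd"`, `"ddg"`, or
#'   `"hdg"`.
#' @param params Model parameters (see [generate_model()]); a default
#'   Gaussian kernel of width 30 mm is supplied for the drop-off models.
#' @param seed Integer seed; all randomness flows from it.
#' @param shell_radius,jitter_sd Shell radius and radial jitter (mm). The
#'   default jitter (15 mm on a 60 mm shell) makes the cloud volume-like
#'   enough for the spatial-density heterogeneity that drives hierarchy in
#'   embedded models, while keeping a clear bilateral geometry.
#' @return An object of class `surrogate_brain`: a list with `graph`,
#'   `coords` (with `hemisphere` attribute), and `truth`.
#' @export
make_surrogate <- function(n, m, model = "hdg", params = list(),
                           seed = 1, shell_radius = 60, jitter_sd = 15) {
  if (n %% 2 != 0) stop("`n` must be even (two hemispheres)",
                        call. = FALSE)
  model <- tolower(model)
  if (!model %in% c("rg", "mw", "dd", "ddg", "hdg"))
    stop("`model` must be an embedded model code", call. = FALSE)
  set.seed(seed)
  nh <- n / 2
  # right-hemisphere points on a jittered shell, x kept positive
  u <- runif(nh, -1, 1)
  phi <- runif(nh, 0, 2 * pi)
  rad <- shell_radius + rnorm(nh, 0, jitter_sd)
  pts <- cbind(x = abs(rad * sqrt(1 - u^2) * cos(phi)) + 8,
               y = rad * sqrt(1 - u^2) * sin(phi),
               z = rad * u)
  coords <- rbind(pts, pts * matrix(c(-1, 1, 1), nh, 3, byrow = TRUE))
  attr(coords, "hemisphere") <- rep(c("R", "L"), each = nh)
  if (model %in% c("dd", "ddg", "hdg") && is.null(params$kernel))
    params$kernel <- kernel_gaussian(30)
  graph <- generate_model(model, n = n, m = m, coords = coords,
                          params = params)
  if (model == "rg") {
    coords <- attr(graph, "coords")
    attr(graph, "coords") <- NULL
  }
  out <- list(graph = graph, coords = coords,
              truth = list(model = model, n = n, m = m, params = params,
                           seed = seed, shell_radius = shell_radius,
                           jitter_sd = jitter_sd))
  class(out) <- "surrogate_brain"
  out
}

#' @export
print.surrogate_brain <- function(x, ...) {
  cat(sprintf("Synthetic pseudo-brain: %d nodes, %d edges, model %s (seed %d)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$truth$model, x$truth$seed))
  invisible(x)
}

#' Regenerate a surrogate from its recorded truth
#'
#' @param truth The `truth` list of a `surrogate_brain`.
#' @return A `surrogate_brain`, bit-identical to the original.
#' @export
regenerate_surrogate <- function(truth) {
  make_surrogate(truth$n, truth$m, truth$model, truth$params,
                 seed = truth$seed, shell_radius = truth$shell_radius,
                 jitter_sd = truth$jitter_sd)
}
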