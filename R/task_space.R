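#' Construct a task space from meta-analytic recruitment probabilities
#'
#' Builds a discrete experiment space in which each candidate task is placed
#' at the coordinates given by its probability of recruiting two brain-network
#' components, \eqn{(\Pr(\mathrm{comp}_A \mid \mathrm{task}),
#' \Pr(\mathrm{comp}_B \mid \mathrm{task}))}. The space covers the unit square
#' and candidates are ordered lexicographically by task id, which fixes all
#' downstream argmax tie-breaks.
#'
#' @param table Data frame with a `task_id` column and one numeric column per
#'   component, each entry a probability in \[0, 1\].
#' @param components Character or integer vector of length 2 selecting the two
#'   component columns that span the space (x axis first).
#' @param name Name for the space.
#' @param grid_resolution Number of grid points per dimension used by
#'   [prediction_grid()].
#' @return A `task_space` object: list with elements `name`, `dim`,
#'   `candidates` (data frame `id`, `x1`, `x2`), `bounds` and
#'   `grid_resolution`.
#' @seealso [task_space_parametric()], [hypothesized_predictions()]
#' @examples
#' tab <- data.frame(task_id = c("A", "B"), dfpn = c(0, 1), vfpn = c(0, 1))
#' sp <- task_space_from_probabilities(tab, c("dfpn", "vfpn"))
#' sp$candidates
#' @export
task_space_from_probabilities <- function(table, components,
                                          name = "metaanalytic",
                                          grid_resolution = 50L) {
  stopifnot(is.data.frame(table), "task_id" %in% names(table))
  if (nrow(table) < 2L)
    stop("need at least 2 tasks to span a space")
  if (length(components) != 2L)
    stop("'components' must select exactly two component columns")
  ids <- as.character(table$task_id)
  if (anyDuplicated(ids))
    stop("duplicate task ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids)))
    stop("task ids must be nonempty")
  comp_cols <- if (is.numeric(components)) {
    setdiff(names(table), "task_id")[components]
  } else {
    as.character(components)
  }
  if (any(is.na(comp_cols)) || !all(comp_cols %in% names(table)))
    stop("component columns not found in table")
  p <- as.matrix(table[, comp_cols, drop = FALSE])
  storage.mode(p) <- "double"
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("recruitment probabilities must be finite and in [0, 1]")
  ord <- order(ids)
  cand <- data.frame(id = ids[ord], x1 = p[ord, 1L], x2 = p[ord, 2L],
                     stringsAsFactors = FALSE)
  new_task_space(name = name, dim = 2L, candidates = cand,
                 bounds = matrix(c(0, 1, 0, 1), nrow = 2L,
                                 dimnames = list(c("lo", "hi"), NULL)),
                 grid_resolution = as.integer(grid_resolution))
}

#' Construct a parametric task space from difficulty levels
#'
#' Builds the full factorial grid over one or two parametric task dimensions
#' (e.g. 16 difficulty levels, or 8 step counts crossed with 2 convolution
#' conditions). Each dimension's levels are mapped linearly onto \[0, 1\] so
#' that a single kernel lengthscale scale applies across spaces.
#'
#' @param levels Integer vector (length 1 or 2) of level counts per dimension.
#' @param name Name for the space.
#' @param grid_resolution Grid points per dimension for [prediction_grid()].
#' @return A `task_space` object. Candidate ids are `"L<i>"` for 1D spaces and
#'   `"L<i>_C<j>"` for 2D spaces, zero-padded so lexicographic id order equals
#'   grid order.
#' @examples
#' task_space_parametric(16)$candidates[1:3, ]
#' nrow(task_space_parametric(c(8, 2))$candidates)
#' @export
task_space_parametric <- function(levels, name = "parametric",
                                  grid_resolution = 50L) {
  levels <- as.integer(levels)
  if (length(levels) < 1L || length(levels) > 2L)
    stop("'levels' must have length 1 or 2")
  if (any(levels < 1L))
    stop("level counts must be >= 1")
  if (prod(levels) < 2L)
    stop("need at least 2 candidates in total")
  unit_axis <- function(k) if (k == 1L) 0 else seq(0, 1, length.out = k)
  pad <- function(i, k) formatC(i, width = nchar(k), flag = "0")
  if (length(levels) == 1L) {
    cand <- data.frame(
      id = paste0("L", pad(seq_len(levels), levels)),
      x1 = unit_axis(levels),
      stringsAsFactors = FALSE)
    dim <- 1L
    bounds <- matrix(c(0, 1), nrow = 2L,
                     dimnames = list(c("lo", "hi"), NULL))
  } else {
    g <- expand.grid(i = seq_len(levels[1L]), j = seq_len(levels[2L]))
    cand <- data.frame(
      id = paste0("L", pad(g$i, levels[1L]), "_C", pad(g$j, levels[2L])),
      x1 = unit_axis(levels[1L])[g$i],
      x2 = unit_axis(levels[2L])[g$j],
      stringsAsFactors = FALSE)
    dim <- 2L
    bounds <- matrix(c(0, 1, 0, 1), nrow = 2L,
                     dimnames = list(c("lo", "hi"), NULL))
  }
  cand <- cand[order(cand$id), , drop = FALSE]
  rownames(cand) <- NULL
  new_task_space(name = name, dim = dim, candidates = cand, bounds = bounds,
                 grid_resolution = as.integer(grid_resolution))
}

new_task_space <- function(name, dim, candidates, bounds, grid_resolution) {
  coord_cols <- paste0("x", seq_len(dim))
  xy <- as.matrix(candidates[, coord_cols, drop = FALSE])
  if (any(!is.finite(xy)))
    stop("candidate coordinates must be finite")
  for (d in seq_len(dim)) {
    if (any(xy[, d] < bounds["lo", d] - 1e-12) ||
        any(xy[, d] > bounds["hi", d] + 1e-12))
      stop("candidate coordinates outside bounds in dimension ", d)
  }
  structure(list(name = name, dim = dim, candidates = candidates,
                 bounds = bounds, grid_resolution = grid_resolution),
            class = "task_space")
}

#' @export
print.task_space <- function(x, ...) {
  cat("Task space '", x$name, "': ", nrow(x$candidates), " candidates in ",
      x$dim, "D\n", sep = "")
  print(utils::head(x$candidates, 6L))
  if (nrow(x$candidates) > 6L) cat("...\n")
  invisible(x)
}

# coordinate matrix (n x dim) of a space's candidates
space_coords <- function(space) {
  as.matrix(space$candidates[, paste0("x", seq_len(space$dim)), drop = FALSE])
}

#' Hypothesized contrast predictions from recruitment probabilities
#'
#' Scores every task by the meta-analytic prediction of the target contrast:
#' either the pairwise difference \eqn{\Pr(\mathrm{target}\mid t) -
#' \Pr(\mathrm{other}\mid t)} or the one-versus-mean form
#' \eqn{\Pr(\mathrm{target}\mid t) - \mathrm{mean}_j \Pr(\mathrm{other}_j \mid t)}.
#'
#' @param table Data frame as in [task_space_from_probabilities()].
#' @param target Column (name or index among component columns) of the target
#'   component.
#' @param others Columns of the component(s) contrasted against. One column
#'   gives the pairwise form; several give one-versus-mean.
#' @return Named numeric vector of scores, one per task, sorted by task id.
#' @examples
#' tab <- data.frame(task_id = c("A", "B"),
#'                   c09 = c(0.9, 0.2), c08 = c(0.3, 0.2))
#' hypothesized_predictions(tab, "c09", "c08")
#' @export
hypothesized_predictions <- function(table, target, others) {
  stopifnot(is.data.frame(table), "task_id" %in% names(table))
  comp_names <- setdiff(names(table), "task_id")
  as_col <- function(x) if (is.numeric(x)) comp_names[x] else as.character(x)
  target <- as_col(target)
  others <- as_col(others)
  if (any(is.na(c(target, others))) ||
      !all(c(target, others) %in% comp_names))
    stop("component columns not found in table")
  if (target %in% others)
    stop("target component cannot appear among 'others'")
  ids <- as.character(table$task_id)
  p_t <- as.numeric(table[[target]])
  p_o <- rowMeans(as.matrix(table[, others, drop = FALSE]))
  score <- p_t - p_o
  names(score) <- ids
  score[order(names(score))]
}

#' Dense prediction grid over a task space
#'
#' Regular lattice of `grid_resolution^dim` points covering the space bounds,
#' in row-major order (first dimension varying fastest), used for rendering
#' posterior prediction maps.
#'
#' @param space A `task_space`.
#' @param resolution Optional override of the space's `grid_resolution`.
#' @return Numeric matrix with `dim` columns.
#' @export
prediction_grid <- function(space, resolution = NULL) {
  stopifnot(inherits(space, "task_space"))
  res <- if (is.null(resolution)) space$grid_resolution else as.integer(resolution)
  if (res < 2L) stop("grid resolution must be >= 2")
  axes <- lapply(seq_len(space$dim), function(d)
    seq(space$bounds["lo", d], space$bounds["hi", d], length.out = res))
  g <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- paste0("x", seq_len(space$dim))
  g
}

#' Read a task probability table from CSV
#'
#' Expects a header `task_id, <component>, <component>, ...` with
#' probabilities in \[0, 1\].
#'
#' @param path Path to a CSV file.
#' @return Data frame suitable for [task_space_from_probabilities()].
#' @export
read_task_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"task_id" %in% names(tab))
    stop("task table must have a 'task_id' column")
  tab
}

#' Serialize / restore a task space as JSON
#'
#' @param space A `task_space`.
#' @param path Output (input) file path.
#' @return `write_task_space` returns `path` invisibly; `read_task_space`
#'   returns a `task_space`.
#' @export
write_task_space <- function(space, path) {
  stopifnot(inherits(space, "task_space"))
  obj <- list(name = space$name, dim = space$dim,
              candidates = space$candidates,
              bounds = list(lo = unname(space$bounds["lo", ]),
                            hi = unname(space$bounds["hi", ])),
              grid_resolution = space$grid_resolution)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_task_space
#' @export
read_task_space <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bounds <- rbind(lo = obj$bounds$lo, hi = obj$bounds$hi)
  new_task_space(name = obj$name, dim = as.integer(obj$dim),
                 candidates = as.data.frame(obj$candidates),
                 bounds = bounds,
                 grid_resolution = as.integer(obj$grid_resolution))
}
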