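#' Y-maze geometry
#'
#' Describes a symmetric three-arm maze: arms of equal length radiating from
#' a central junction at 120 degree separation. Distances are in cm; arm
#' depth is measured from the maze center along the arm axis, so the arm
#' terminal lies at `arm_length` from the center.
#'
#' @param arm_length Arm length from center to terminal, cm (default 45).
#' @param arm_width Arm width, cm (default 8). Retained for completeness;
#'   the body-center analyses only use the axial projection.
#' @param arms Arm labels, default `c("A", "B", "C")`.
#' @return An object of class `maze_geometry`: a list with `arm_length`,
#'   `arm_width`, `arms`, and `directions` (unit vectors per arm).
#' @examples
#' g <- maze_geometry()
#' g$directions
#' @export
maze_geometry <- function(arm_length = 45, arm_width = 8,
                          arms = c("A", "B", "C")) {
  check_pos(arm_length, "arm_length")
  check_pos(arm_width, "arm_width")
  n <- length(arms)
  if (n != 3L) stop("a Y-maze has exactly 3 arms")
  ang <- pi / 2 + (seq_len(n) - 1L) * 2 * pi / n
  dirs <- cbind(cos(ang), sin(ang))
  rownames(dirs) <- arms
  colnames(dirs) <- c("x", "y")
  structure(list(arm_length = arm_length, arm_width = arm_width,
                 arms = arms, directions = dirs),
            class = "maze_geometry")
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf("Y-maze: %d arms (%s), %g cm x %g cm\n",
              length(x$arms), paste(x$arms, collapse = ""),
              x$arm_length, x$arm_width))
  invisible(x)
}

#' Per-sample arm assignment and depth along the arm axis
#'
#' For each (x, y) sample returns the arm whose axis projection is largest
#' and that projection (cm from the center). Points near the center project
#' weakly onto all arms.
#' @noRd
arm_projection <- function(xy, geometry) {
  p <- xy %*% t(geometry$directions)   # n x 3 projections
  k <- max.col(p, ties.method = "first")
  list(arm = geometry$arms[k], depth = p[cbind(seq_len(nrow(p)), k)])
}
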