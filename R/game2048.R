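# The engagement task: a faithful 2048 engine. In the adherence experiment
# the game stands in for "everyday life"; illness (screen blur) interrupts
# it and code entry (the medication analog) restores it.
#
# Conventions follow the open-source original: new games start with two
# spawned tiles; spawns are 90% a 2 and 10% a 4 on a uniformly chosen empty
# cell; each tile merges at most once per move, resolved from the edge the
# tiles move toward; a move that changes nothing spawns no tile.

GRID_N <- 4L
MOVE_DIRECTIONS <- c("up", "down", "left", "right")

#' Start a new 2048 game
#'
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (the caller is responsible for seeding).
#' @return A `game_state`: list with `grid` (4x4 integer matrix, 0 = empty),
#'   `score`, `move_count`, and `over`.
#' @examples
#' g <- new_game(seed = 1)
#' sum(g$grid > 0)  # exactly two tiles
#' @export
new_game <- function(seed = NULL) {
  with_seed(seed, {
    grid <- matrix(0L, GRID_N, GRID_N)
    grid <- spawn_tile(grid)
    grid <- spawn_tile(grid)
    structure(
      list(grid = grid, score = 0L, move_count = 0L, over = FALSE),
      class = "game_state"
    )
  })
}

# Spawn one tile (90% value 2, 10% value 4) on a uniformly chosen empty cell.
spawn_tile <- function(grid) {
  empty <- which(grid == 0L)
  if (length(empty) == 0L) stop("no empty cell to spawn on", call. = FALSE)
  cell <- if (length(empty) == 1L) empty else empty[sample.int(length(empty), 1L)]
  grid[cell] <- if (stats::runif(1) < 0.9) 2L else 4L
  grid
}

# Slide one row toward index 1, merging equal neighbours nearest the target
# edge first; each result tile merges at most once. Returns the new row and
# the score gained (sum of created tile values).
slide_row <- function(row) {
  nz <- row[row != 0L]
  out <- integer(0)
  gained <- 0L
  i <- 1L
  while (i <= length(nz)) {
    if (i < length(nz) && nz[i] == nz[i + 1L]) {
      v <- nz[i] * 2L
      out <- c(out, v)
      gained <- gained + v
      i <- i + 2L
    } else {
      out <- c(out, nz[i])
      i <- i + 1L
    }
  }
  list(row = c(out, integer(GRID_N - length(out))), gained = gained)
}

# Slide the whole grid; direction is mapped onto row-wise left slides by
# transposition/reversal. Returns grid + total score gained.
slide_grid <- function(grid, dir) {
  flip <- function(m) m[, GRID_N:1L, drop = FALSE]
  gained <- 0L
  oriented <- switch(dir,
    left  = grid,
    right = flip(grid),
    up    = t(grid),
    down  = flip(t(grid))
  )
  for (r in seq_len(GRID_N)) {
    s <- slide_row(oriented[r, ])
    oriented[r, ] <- s$row
    gained <- gained + s$gained
  }
  out <- switch(dir,
    left  = oriented,
    right = flip(oriented),
    up    = t(oriented),
    down  = t(flip(oriented))
  )
  list(grid = out, gained = gained)
}

#' Apply one move to a game state
#'
#' Tiles slide toward `dir`; equal adjacent tiles merge pairwise (each result
#' tile merges at most once per move) and the score increases by the sum of
#' the created tile values. If the move changed the grid, one tile spawns on
#' a uniformly chosen empty cell and `move_count` increments; a no-effect
#' move leaves the state untouched. The game-over flag is recomputed.
#'
#' @param state A `game_state`.
#' @param dir One of `"up"`, `"down"`, `"left"`, `"right"`.
#' @param seed Optional seed for the spawn draw.
#' @return The updated `game_state`.
#' @export
apply_move <- function(state, dir, seed = NULL) {
  stopifnot(inherits(state, "game_state"))
  dir <- match.arg(dir, MOVE_DIRECTIONS)
  if (state$over) stop("cannot move: game is over", call. = FALSE)
  with_seed(seed, {
    s <- slide_grid(state$grid, dir)
    if (!identical(s$grid, state$grid)) {
      state$grid <- spawn_tile(s$grid)
      state$score <- state$score + s$gained
      state$move_count <- state$move_count + 1L
      state$over <- !any_move_possible(state$grid)
    }
    state
  })
}

# TRUE iff some slide or merge is available.
any_move_possible <- function(grid) {
  if (any(grid == 0L)) return(TRUE)
  horiz <- grid[, -GRID_N, drop = FALSE] == grid[, -1L, drop = FALSE]
  vert  <- grid[-GRID_N, , drop = FALSE] == grid[-1L, , drop = FALSE]
  any(horiz) || any(vert)
}

#' Test whether a game is finished
#'
#' A game is over iff the grid has no empty cell and no equal
#' orthogonally-adjacent pair.
#'
#' @param state A `game_state` or a bare 4x4 grid matrix.
#' @return Logical scalar.
#' @export
is_over <- function(state) {
  grid <- if (inherits(state, "game_state")) state$grid else state
  stopifnot(is.matrix(grid), all(dim(grid) == GRID_N))
  !any_move_possible(grid)
}

#' Restart a finished game, otherwise return the state unchanged
#'
#' The session-level cumulative score is the caller's responsibility: the
#' harness banks `state$score` before restarting so session earnings are
#' monotone across plays.
#'
#' @inheritParams apply_move
#' @return A `game_state` (fresh two-tile grid if `state$over`).
#' @export
restart_if_over <- function(state, seed = NULL) {
  stopifnot(inherits(state, "game_state"))
  if (!state$over) return(state)
  new_game(seed = seed)
}

#' List the legal move directions for a state
#'
#' @param state A `game_state`.
#' @return Character vector, subset of `c("up", "down", "left", "right")`.
#' @export
legal_moves <- function(state) {
  stopifnot(inherits(state, "game_state"))
  MOVE_DIRECTIONS[vapply(
    MOVE_DIRECTIONS,
    function(d) !identical(slide_grid(state$grid, d)$grid, state$grid),
    logical(1)
  )]
}

#' @export
print.game_state <- function(x, ...) {
  cat(sprintf("2048 game: score %d, moves %d%s\n",
              x$score, x$move_count, if (x$over) " (over)" else ""))
  print(x$grid)
  invisible(x)
}
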