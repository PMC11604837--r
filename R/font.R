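# Minimal embedded 5x7 bitmap font (digits, '.', '-', '/', 'm', 's', '*')
# for color-bar tick labels and unit strings. Embedding the glyphs keeps
# rendered panels bit-identical across systems, which the test suite relies
# on. Unknown characters render as a hollow box.

.FONT5x7 <- local({
  g <- function(...) {
    rows <- c(...)
    m <- matrix(0L, 7L, 5L)
    for (i in seq_len(7L)) {
      m[i, ] <- as.integer(strsplit(rows[i], "")[[1L]] == "#")
    }
    m
  }
  list(
    "0" = g(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
    "1" = g("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
    "2" = g(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
    "3" = g(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
    "4" = g("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
    "5" = g("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
    "6" = g("..##.", ".#...", "#....", "####.", "#...#", "#...#", ".###."),
    "7" = g("#####", "....#", "...#.", "..#..", "..#..", "..#..", "..#.."),
    "8" = g(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
    "9" = g(".###.", "#...#", "#...#", ".####", "....#", "...#.", ".##.."),
    "." = g(".....", ".....", ".....", ".....", ".....", ".##..", ".##.."),
    "-" = g(".....", ".....", ".....", ".###.", ".....", ".....", "....."),
    "/" = g("....#", "....#", "...#.", "..#..", ".#...", "#....", "#...."),
    "m" = g(".....", ".....", "##.#.", "#.#.#", "#.#.#", "#.#.#", "#.#.#"),
    "s" = g(".....", ".....", ".####", "#....", ".###.", "....#", "####."),
    "*" = g(".....", "#.#.#", ".###.", "#####", ".###.", "#.#.#", "....."),
    " " = matrix(0L, 7L, 5L),
    "?" = g("#####", "#...#", "#...#", "#...#", "#...#", "#...#", "#####")
  )
})

# Rasterize a string to a 0/1 matrix (7*scale rows).
.rasterize_text <- function(text, scale = 1L) {
  chars <- strsplit(text, "")[[1L]]
  if (length(chars) == 0L) return(matrix(0L, 7L * scale, 0L))
  glyphs <- lapply(chars, function(ch) {
    m <- .FONT5x7[[ch]]
    if (is.null(m)) m <- .FONT5x7[["?"]]
    cbind(m, 0L) # 1-pixel inter-character gap
  })
  m <- do.call(cbind, glyphs)
  m <- m[, -ncol(m), drop = FALSE]
  if (scale > 1L) {
    m <- m[rep(seq_len(nrow(m)), each = scale),
           rep(seq_len(ncol(m)), each = scale), drop = FALSE]
  }
  m
}

# Blit a 0/1 mask into an h x w x 3 array at (row, col) top-left, clipping
# at the canvas edges.
.blit <- function(canvas, mask, row, col, color = c(1, 1, 1)) {
  h <- dim(canvas)[1L]; w <- dim(canvas)[2L]
  for (i in seq_len(nrow(mask))) {
    r <- row + i - 1L
    if (r < 1L || r > h) next
    on <- which(mask[i, ] == 1L)
    cc <- col + on - 1L
    cc <- cc[cc >= 1L & cc <= w]
    if (length(cc)) {
      canvas[r, cc, 1L] <- color[1L]
      canvas[r, cc, 2L] <- color[2L]
      canvas[r, cc, 3L] <- color[3L]
    }
  }
  canvas
}
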