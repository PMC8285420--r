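# Built-in 5x7 bitmap font for pixel burn-in. Glyphs are enumerable, which
# lets tests count exactly which pixels an annotation touched. Rows are
# strings of '.'/'#'; unknown characters fall back to the solid block.

FONT5X7 <- list(
  "A" = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "B" = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  "C" = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
  "D" = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
  "E" = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
  "F" = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  "G" = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
  "H" = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "I" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####"),
  "J" = c("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
  "K" = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
  "L" = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  "M" = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
  "N" = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  "O" = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "P" = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  "Q" = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
  "R" = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  "S" = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  "T" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  "U" = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "V" = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  "W" = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
  "X" = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
  "Y" = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
  "Z" = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
  "0" = c(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
  "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", "#####"),
  "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
  "3" = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
  "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
  "5" = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
  "6" = c(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###."),
  "7" = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
  "8" = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
  "9" = c(".###.", "#...#", "#...#", ".####", "....#", "....#", ".###."),
  " " = c(".....", ".....", ".....", ".....", ".....", ".....", "....."),
  "^" = c("..#..", ".#.#.", "#...#", ".....", ".....", ".....", "....."),
  "." = c(".....", ".....", ".....", ".....", ".....", ".##..", ".##.."),
  "," = c(".....", ".....", ".....", ".....", ".##..", "..#..", ".#..."),
  "-" = c(".....", ".....", ".....", "#####", ".....", ".....", "....."),
  "/" = c("....#", "....#", "...#.", "..#..", ".#...", "#....", "#...."),
  ":" = c(".....", ".##..", ".##..", ".....", ".##..", ".##..", "....."),
  "(" = c("..#..", ".#...", "#....", "#....", "#....", ".#...", "..#.."),
  ")" = c("..#..", "...#.", "....#", "....#", "....#", "...#.", "..#..")
)

FONT_FALLBACK <- c("#####", "#####", "#####", "#####", "#####", "#####", "#####")
GLYPH_H <- 7L
GLYPH_W <- 5L
GLYPH_LEAD <- 1L   # blank rows between stacked lines
GLYPH_GAP <- 1L    # blank columns between glyphs

glyph_matrix <- function(ch) {
  g <- FONT5X7[[toupper(ch)]]
  if (is.null(g)) g <- FONT_FALLBACK
  m <- do.call(rbind, strsplit(g, ""))
  m == "#"
}

# Logical mask (rows x cols) with TRUE at glyph pixels for multi-line text,
# integrally scaled. Lines are stacked with fixed leading.
render_text_mask <- function(text, rows, cols, scale = 1L) {
  scale <- as.integer(scale)
  stopifnot(scale >= 1L)
  mask <- matrix(FALSE, nrow = rows, ncol = cols)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!length(lines)) return(mask)
  line_h <- (GLYPH_H + GLYPH_LEAD) * scale
  need_h <- length(lines) * line_h - GLYPH_LEAD * scale
  widths <- (nchar(lines) * (GLYPH_W + GLYPH_GAP) - GLYPH_GAP) * scale
  if (need_h > rows || max(widths) > cols) {
    fail_with("text does not fit the burn-in region at scale %d", scale)
  }
  for (li in seq_along(lines)) {
    chars <- strsplit(lines[li], "")[[1]]
    r0 <- (li - 1L) * line_h
    for (ci in seq_along(chars)) {
      g <- glyph_matrix(chars[ci])
      if (!any(g)) next
      c0 <- (ci - 1L) * (GLYPH_W + GLYPH_GAP) * scale
      big <- g[rep(seq_len(GLYPH_H), each = scale),
               rep(seq_len(GLYPH_W), each = scale), drop = FALSE]
      mask[r0 + seq_len(GLYPH_H * scale), c0 + seq_len(GLYPH_W * scale)] <-
        mask[r0 + seq_len(GLYPH_H * scale), c0 + seq_len(GLYPH_W * scale)] | big
    }
  }
  mask
}
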