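# Bundled fixed-width 5 x 7 bitmap font covering the letters produced by the
# pseudo-Latin syllable grammar.  No typeface shaping; glyphs are block
# capitals rendered for lowercase input.

FONT5x7 <- list(
  a = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  b = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  c = c(".####", "#....", "#....", "#....", "#....", "#....", ".####"),
  d = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
  e = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
  f = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  g = c(".####", "#....", "#....", "#.###", "#...#", "#...#", ".###."),
  i = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####"),
  l = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  m = c("#...#", "##.##", "#.#.#", "#...#", "#...#", "#...#", "#...#"),
  n = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  o = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  p = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  r = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  s = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  t = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  u = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  v = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#..")
)

glyph_bitmap <- function(ch) {
  rows <- FONT5x7[[ch]]
  if (is.null(rows)) stopf("no glyph for character '%s'", ch)
  m <- matrix(FALSE, 7L, 5L)
  for (j in 1:7) m[j, ] <- strsplit(rows[j], "")[[1]] == "#"
  m
}
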