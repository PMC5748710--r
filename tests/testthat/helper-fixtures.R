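write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# four-node toy network used across scoring tests:
#   g-a 400, g-b 700, g-c 999, a-b 500
toy_network <- function() {
  ppi_network(data.frame(p1 = c("g", "g", "g", "a"),
                         p2 = c("a", "b", "c", "b"),
                         score = c(400L, 700L, 999L, 500L)))
}
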