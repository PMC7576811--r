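# random unit-mass spectrum with 1..25 peaks, for property-style tests
random_spectrum <- function(seed, min_peaks = 1, max_peaks = 25,
                            max_mz = 300) {
  set.seed(seed)
  n <- sample(min_peaks:max_peaks, 1)
  mz <- sort(sample(26:max_mz, n))
  intensity <- stats::runif(n, 0.5, 999)
  spectrum(mz, intensity, meta = list(name = paste0("rand", seed)))
}

# build a V2000 Molfile text from elements and a bond table (i, j, order);
# coordinates are dummies — only connectivity matters here
make_molfile <- function(elements, bonds, name = "fixture") {
  n <- length(elements)
  b <- as.data.frame(bonds)
  lines <- c(
    name, "  fixture", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            seq_len(n), 0, 0, elements),
    if (nrow(b) > 0)
      sprintf("%3d%3d%3d  0", b[[1]], b[[2]], b[[3]]),
    "M  END"
  )
  lines
}

# furan: 4 aromatic C + ring O, 5 aromatic ring bonds
furan_molfile <- function() {
  make_molfile(c("C", "C", "C", "C", "O"),
               data.frame(i = 1:5, j = c(2:5, 1), order = 4),
               name = "furan")
}

# toy single-CO-loss / double-CO-loss ensemble for the cyclobutenedione
# worked example: parent m/z 82; channels keep charge on the organic
# fragment because CO has the far higher ionization potential
cyclobutenedione_ensemble <- function(n_intact = 4, n_co = 3, n_2co = 2) {
  gen_ensemble(
    channels = list(
      list(mass = 82, ip = 9.6),                        # intact [M]+.
      list(mass = c(54, 28), ip = c(9.0, 14.0)),        # [M-CO]+. + CO
      list(mass = c(26, 28, 28), ip = c(11.4, 14.0, 14.0))  # [M-2CO]+.
    ),
    n_events = c(n_intact, n_co, n_2co),
    parent_mass = 82, seed = 7
  )
}
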