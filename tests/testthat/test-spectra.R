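tab <- eiip_table()

make_spectrum <- function(values, n_points = 64, seq_id = "s") {
  ns <- structure(list(seq_id = seq_id, residues = strrep("A", length(values)),
                       values = values, length = length(values)),
                  class = "numerical_sequence")
  amplitude_spectrum(ns, n_points = n_points)
}

test_that("spectrum grid follows the transform length and excludes DC", {
  ns <- encode_sequence(strrep("ARND", 25), tab)  # length 100
  sp <- amplitude_spectrum(ns, n_points = 512)
  expect_length(sp$frequencies, 256L)
  expect_equal(sp$frequencies[1], 1 / 512)        # no zero bin
  expect_equal(diff(sp$frequencies), rep(1 / 512, 255))
  expect_equal(max(sp$frequencies), 0.5)
  expect_true(all(sp$amplitudes >= 0))
  expect_error(amplitude_spectrum(ns, n_points = 64), "smaller than sequence length")
})

test_that("transform length is the padded power of two with a 512 floor", {
  expect_equal(rrm_transform_length(100), 512L)
  expect_equal(rrm_transform_length(c(100, 700)), 1024L)
  expect_equal(rrm_transform_length(513), 1024L)
  expect_equal(rrm_transform_length(512), 512L)
})

test_that("a constant signal yields an all-zero, degenerate spectrum", {
  sp <- amplitude_spectrum(encode_sequence("LLLLLLLLLL", tab), n_points = 512)
  expect_true(sp$degenerate)
  expect_true(all(sp$amplitudes == 0))
})

test_that("a planted cosine peaks at its frequency bin (direct-DFT oracle)", {
  # EIIP-scale cosine at 8 cycles over 64 points -> f = 0.125
  i <- 0:63
  x <- 0.06 + 0.05 * cos(2 * pi * 8 * i / 64)
  sp <- make_spectrum(x, n_points = 64)
  expect_equal(sp$frequencies[which.max(sp$amplitudes)], 0.125)
  expect_equal(sp$amplitudes, dft_amplitude_oracle(x, 64), tolerance = 1e-10)
  # quantized to actual residues the peak stays put
  res <- vapply(x, nearest_residue_oracle, "", entries = tab$entries)
  spq <- amplitude_spectrum(encode_sequence(paste(res, collapse = ""), tab),
                            n_points = 64)
  expect_equal(spq$frequencies[which.max(spq$amplitudes)], 0.125)
})

test_that("consensus is the elementwise product of member spectra", {
  set.seed(31)
  sps <- lapply(1:4, function(j)
    make_spectrum(runif(64, 0, 0.12), seq_id = paste0("s", j)))
  cs <- cross_spectrum(sps, group_id = "g")
  expect_equal(cs$amplitudes, Reduce(`*`, lapply(sps, `[[`, "amplitudes")))
  expect_equal(cs$n_members, 4L)
  # identical members: consensus = A^n at every bin
  cs3 <- cross_spectrum(list(sps[[1]], sps[[1]], sps[[1]]))
  expect_equal(cs3$amplitudes, sps[[1]]$amplitudes^3)
  # absorbing zero
  z <- sps[[2]]; z$amplitudes[10] <- 0
  expect_equal(cross_spectrum(list(sps[[1]], z))$amplitudes[10], 0)
  # permutation invariance (bitwise)
  expect_identical(cross_spectrum(sps[c(3, 1, 4, 2)])$amplitudes, cs$amplitudes)
  # duplicating the whole group squares the consensus
  expect_equal(cross_spectrum(c(sps, sps))$amplitudes, cs$amplitudes^2)
})

test_that("consensus rejects mismatched grids and trivial groups", {
  a <- make_spectrum(runif(50, 0, 0.1), n_points = 64)
  b <- make_spectrum(runif(50, 0, 0.1), n_points = 128)
  expect_error(cross_spectrum(list(a, b)), "mismatched")
  expect_error(cross_spectrum(list(a)), "fewer than 2")
})

test_that("characteristic peak reports argmax, S/N and significance", {
  cs <- structure(list(group_id = "g", frequencies = (1:32) / 64,
                       amplitudes = rep(2, 32), n_members = 2L, n_points = 64L),
                  class = "consensus_spectrum")
  flat <- find_characteristic_frequency(cs, snr_threshold = 20)
  expect_equal(flat$snr, 1)
  expect_false(flat$significant)
  # tie at two bins resolved toward the lowest frequency
  cs$amplitudes[c(5, 9)] <- 10
  expect_equal(find_characteristic_frequency(cs)$frequency, 5 / 64)
  cs$amplitudes[] <- 0
  expect_error(find_characteristic_frequency(cs), "degenerate consensus")
})

test_that("scaling every member by c scales the consensus by c^n, argmax fixed", {
  set.seed(77)
  grp <- generate_protein_group(protein_group_spec(seed = 77), table = tab)
  enc <- lapply(seq_along(grp$sequences), function(j)
    encode_sequence(grp$sequences[[j]], tab, seq_id = paste0("s", j)))
  n <- rrm_transform_length(vapply(enc, `[[`, 0L, "length"))
  sps <- lapply(enc, amplitude_spectrum, n_points = n)
  cs1 <- cross_spectrum(sps)
  scaled <- lapply(enc, function(e) { e$values <- e$values * 2.5; e })
  cs2 <- cross_spectrum(lapply(scaled, amplitude_spectrum, n_points = n))
  expect_equal(cs2$amplitudes, cs1$amplitudes * 2.5^length(sps),
               tolerance = 1e-9)
  expect_equal(which.max(cs2$amplitudes), which.max(cs1$amplitudes))
})

test_that("FASTA round trip preserves ids and sequences", {
  grp <- generate_protein_group(protein_group_spec(seed = 5), table = tab)
  path <- tempfile(fileext = ".fasta")
  on.exit(unlink(path))
  write_fasta_group(grp, path)
  back <- read_fasta_group(path)
  expect_identical(back, grp$sequences)
})
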