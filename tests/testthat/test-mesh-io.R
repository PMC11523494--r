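test_that("PLY/STL/OFF round trips preserve geometry to 1e-6 mm", {
  m <- make_molar(molar_spec("cusped", grid_n = 24, seed = 3))
  td <- withr::local_tempdir()
  for (fmt in c("ply", "stl", "off")) {
    for (bin in if (fmt == "off") FALSE else c(FALSE, TRUE)) {
      f <- file.path(td, sprintf("m_%d.%s", bin, fmt))
      write_mesh(m, f, fmt, binary = bin)
      m2 <- read_mesh(f)
      expect_identical(nrow(m2$faces), nrow(m$faces))
      if (fmt == "stl") {
        # STL welds the triangle soup; vertex order is not contractual
        expect_lt(max(abs(sort(m2$vertices) - sort(m$vertices))), 1e-6)
      } else {
        expect_identical(nrow(m2$vertices), nrow(m$vertices))
        expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
      }
    }
  }
})

test_that("ASCII PLY reader preserves counts and vertex order", {
  td <- withr::local_tempdir()
  tet <- c("ply", "format ascii 1.0", "element vertex 4",
           "property float x", "property float y", "property float z",
           "element face 4", "property list uchar int vertex_indices",
           "end_header",
           "0 0 0", "1 0 0", "0 1 0", "0 0 1",
           "3 0 1 2", "3 0 1 3", "3 0 2 3", "3 1 2 3")
  f <- file.path(td, "tet.ply")
  writeLines(tet, f)
  m <- read_mesh(f)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 4L)
  expect_equal(m$vertices[2, ], c(1, 0, 0))
})

test_that("binary STL of the unit cube reads as 12 faces", {
  td <- withr::local_tempdir()
  f <- file.path(td, "cube.stl")
  write_mesh(cube_mesh(), f, "stl", binary = TRUE)
  m <- read_mesh(f)
  expect_equal(nrow(m$faces), 12L)
  expect_equal(surface_area(m), 6)
})

test_that("PLY scalar fields survive a round trip (ASCII and binary)", {
  m <- make_molar(molar_spec("cusped", grid_n = 20, seed = 1))
  set.seed(2)
  vs <- list(pcv = runif(nrow(m$vertices)))
  fs <- list(dne = runif(nrow(m$faces)))
  td <- withr::local_tempdir()
  for (bin in c(FALSE, TRUE)) {
    f <- file.path(td, sprintf("s%d.ply", bin))
    write_mesh(m, f, "ply", vertex_scalars = vs, face_scalars = fs,
               binary = bin)
    m2 <- read_mesh(f)
    expect_lt(max(abs(attr(m2, "vertex_scalars")$pcv - vs$pcv)), 1e-6)
    expect_lt(max(abs(attr(m2, "face_scalars")$dne - fs$dne)), 1e-6)
  }
})

test_that("format limitations and contract violations are reported", {
  m <- make_molar(molar_spec("cusped", grid_n = 20, seed = 1))
  td <- withr::local_tempdir()
  expect_warning(
    write_mesh(m, file.path(td, "x.stl"), "stl",
               vertex_scalars = list(a = rep(1, nrow(m$vertices)))),
    "no scalar")
  expect_error(
    write_mesh(m, file.path(td, "y.ply"), "ply",
               vertex_scalars = list(a = 1:3)), "length")
  expect_error(
    write_mesh(m, file.path(td, "z.ply"), "ply",
               vertex_scalars = setNames(list(rep(1, nrow(m$vertices))), "")),
    "name")
  bad <- file.path(td, "bad.ply")
  writeLines(c("ply", "format ascii 1.0", "elemen vertex 3"), bad)
  expect_error(read_mesh(bad), "PLY")
  empty <- file.path(td, "empty.ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 0",
               "property float x", "property float y", "property float z",
               "end_header"), empty)
  expect_error(read_mesh(empty), "empty")
  expect_error(read_mesh(file.path(td, "nothere.ply")), "not found")
})
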