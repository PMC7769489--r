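test_that("roles go to objects in order of first touching change", {
  tr <- generate_scenario("put_on_top", seed = 2)
  roles <- assign_roles(tr)
  expect_identical(roles$hand_id, "hand")
  expect_identical(roles$ground_id, "ground")
  expect_length(roles$obj_ids, 2L)           # grasped cube, then support cube
  expect_identical(roles$obj_ids[1], "obj1")
  expect_identical(roles$obj_ids[2], "obj2")
  expect_true(all(diff(roles$birth_frame) > 0))
  # distractor cubes never gain a role
  expect_false(any(grepl("^dist", roles$obj_ids)))
})

test_that("simultaneous touching changes break ties lexicographically", {
  # hand-free scene in which cubes aa and ab lift off the ground in the same
  # frame: aa gets role 1 by id order
  nf <- 40
  ids <- c("g", "h", "ab", "aa")
  coords <- array(NA_real_, c(nf, 4, 6), dimnames = list(NULL, ids, NULL))
  for (f in seq_len(nf)) {
    coords[f, "g", ] <- c(-1, -0.1, -1, 1, 0, 1)
    coords[f, "h", ] <- c(2, 1, 2, 2.1, 1.1, 2.1)
    dy <- if (f >= 20) 0.3 else 0
    coords[f, "ab", ] <- c(0.3, dy, 0, 0.4, 0.1 + dy, 0.1)
    coords[f, "aa", ] <- c(-0.4, dy, 0, -0.3, 0.1 + dy, 0.1)
  }
  tr <- trajectory(coords, fps = 20, hand_id = "h", ground_id = "g")
  roles <- assign_roles(tr)
  expect_identical(roles$obj_ids, c("aa", "ab"))
  expect_equal(roles$birth_frame[1], roles$birth_frame[2])
})

test_that("a static scene has no action", {
  nf <- 30
  coords <- array(NA_real_, c(nf, 3, 6),
                  dimnames = list(NULL, c("g", "h", "a"), NULL))
  for (f in seq_len(nf)) {
    coords[f, "g", ] <- c(-1, -0.1, -1, 1, 0, 1)
    coords[f, "h", ] <- c(2, 1, 2, 2.1, 1.1, 2.1)
    coords[f, "a", ] <- c(0, 0, 0, 0.1, 0.1, 0.1)
  }
  tr <- trajectory(coords, fps = 20, hand_id = "h", ground_id = "g")
  expect_error(assign_roles(tr), "no action detected")
  expect_error(build_esec(tr), "no action detected")
})

test_that("built eSECs have the canonical structure", {
  e <- build_esec(generate_scenario("put_on_top", seed = 4))
  expect_s3_class(e, "esec_matrix")
  expect_equal(nrow(e$mat), 30L)
  expect_identical(rownames(e$mat),
                   as.vector(sapply(c("TNR", "SSR", "DSR"),
                                    function(b) paste0(PAIR_ORDER, ":", b))))
  expect_gte(ncol(e$mat), 2L)
  # adjacent columns always differ somewhere
  for (j in seq_len(ncol(e$mat) - 1))
    expect_true(any(e$mat[, j] != e$mat[, j + 1]))
  # the hand's object-1 TNR row has exactly one contiguous touch block
  r <- rle(e$mat["H,1:TNR", ])
  expect_equal(sum(r$values == "T"), 1L)
  # object 1 lands on object 2 and stays there
  r12 <- rle(e$mat["1,2:TNR", ])
  expect_identical(r12$values[length(r12$values)], "T")
  expect_equal(sum(r12$values == "T"), 1L)
  # unborn roles stay U; object 3 never exists in the scripted scenes
  expect_true(all(e$mat[grep("3", rownames(e$mat)), ] == "U"))
})

test_that("distractor cubes leave the eSEC bit-identical", {
  base <- build_esec(toy_trajectory(0))
  with_d <- build_esec(toy_trajectory(3))
  expect_identical(with_d$mat, base$mat)
})

test_that("event compression is invariant to action tempo", {
  cfg_slow <- simulation_config()
  cfg_slow$durations$mean <- cfg_slow$durations$mean * 1.3
  cfg_slow$durations$max <- cfg_slow$durations$max * 1.5
  for (a in c("put_on_top", "cut", "push")) {
    fast <- build_esec(generate_scenario(a, seed = 9))
    slow <- build_esec(generate_scenario(a, cfg_slow, seed = 9))
    expect_identical(slow$mat, fast$mat)
  }
})

test_that("eSEC TSV round trip is the identity", {
  e <- build_esec(generate_scenario("take_down", seed = 2))
  path <- file.path(tempdir(), "td.tsv")
  write_esec(e, path)
  e2 <- read_esec(path)
  expect_identical(e2$mat, e$mat)
  expect_identical(e2$action_label, "take_down")

  # hand-written fixture with four columns parses
  fix <- file.path(tempdir(), "fix.tsv")
  m <- matrix(base_column(), 30, 4)
  m[1, c(2, 4)] <- "N"; m[1, 3] <- "T"
  writeLines(paste(rownames(esec(m)$mat),
                   apply(m, 1, paste, collapse = "\t"), sep = "\t"), fix)
  expect_equal(ncol(read_esec(fix)$mat), 4L)

  # a 29-row file is rejected
  bad <- file.path(tempdir(), "bad.tsv")
  writeLines(readLines(path)[1:29 + 1], bad)
  expect_error(read_esec(bad), "format error")
})

test_that("constructor validates alphabets and adjacent distinctness", {
  m <- matrix(base_column(), 30, 2)
  expect_error(esec(m), "identical")
  m2 <- m; m2[1, 2] <- "N"
  expect_s3_class(esec(m2), "esec_matrix")
  m3 <- m2; m3[11, 1] <- "MT"  # dynamic symbol in a static row
  expect_error(esec(m3), "invalid")
  expect_error(esec(m2[1:29, ]), "30 rows")
})
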