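p <- relation_params()

test_that("touching detects shared faces and interpenetration, not corners", {
  a <- cube(c(0, 0, 0), c(1, 1, 1))
  expect_identical(touching(a, cube(c(1, 0, 0), c(2, 1, 1)), p), "T")
  expect_identical(touching(a, cube(c(1.5, 0, 0), c(2.5, 1, 1)), p), "N")
  # face-coincident in x but disjoint in y: the overlap clause fails
  expect_identical(touching(a, cube(c(1, 2, 0), c(2, 3, 1)), p), "N")
  # edge/corner contact is not touching (no strict overlap on two axes)
  expect_identical(touching(a, cube(c(1, 1, 0), c(2, 2, 1)), p), "N")
  # interpenetration counts
  expect_identical(touching(a, cube(c(0.5, 0.5, 0.5), c(1.5, 1.5, 1.5)), p),
                   "T")
  # symmetric in its arguments
  for (i in 1:25) {
    x <- random_cube(); y <- random_cube()
    expect_identical(touching(x, y, p), touching(y, x, p))
  }
})

test_that("candidate sets follow the one-sided directional tests", {
  above <- cube(c(0, 2, 0), c(1, 3, 1))
  below <- cube(c(0, 0, 0), c(1, 1, 1))
  expect_setequal(candidate_static_relations(above, below), "Ab")
  expect_setequal(candidate_static_relations(below, above), "Be")
  # open-top containment
  inner <- cube(c(0.2, 0.5, 0.2), c(0.8, 0.9, 0.8))
  outer <- cube(c(0, 0, 0), c(1, 1, 1))
  expect_true("In" %in% candidate_static_relations(inner, outer))
  expect_true("Sa" %in% candidate_static_relations(outer, inner))
  # diagonal corner contact: Left and Back both hold, and the one-sided
  # above-test admits Ab as well (hand evaluation of the printed tests)
  a <- cube(c(0, 0, 0), c(1, 1, 1))
  b <- cube(c(1, 0, 1), c(2, 1, 2))
  expect_setequal(candidate_static_relations(a, b), c("Ab", "L", "Ba"))
})

test_that("shadow areas are projected rectangle intersections", {
  u1 <- cube(c(0, 0, 0), c(1, 1, 1))
  u2 <- cube(c(0, 2, 0), c(1, 3, 1))
  expect_equal(shadow_area(u2, u1, "Ab"), 1.0)
  off <- cube(c(0.5, 2, 0.5), c(1.5, 3, 1.5))
  expect_equal(shadow_area(off, u1, "Ab"), 0.25)
  far_side <- cube(c(2, 2, 2), c(3, 3, 3))
  expect_error(shadow_area(far_side, u1, "Be"), "domain error")
  disjoint <- cube(c(0, 2, 1), c(1, 3, 2))  # Ab holds, lateral shadow empty
  expect_equal(shadow_area(disjoint, u1, "Ab"), 0)
})

test_that("static relation: shadow selection, Ar collapse, touch upgrades, O", {
  big <- relation_params(far_threshold = 10)
  a_on_b <- cube(c(0, 0.1, 0), c(0.1, 0.2, 0.1))
  b <- cube(c(0, 0, 0), c(0.1, 0.1, 0.1))
  expect_identical(static_relation(a_on_b, b, tnr = "N", big), "Ab")
  expect_identical(static_relation(a_on_b, b, tnr = "T", big), "To")
  expect_identical(static_relation(b, a_on_b, tnr = "T", big), "Bo")
  # a laterally adjacent cube collapses to Around / ArT
  side <- cube(c(0.1, 0, 0), c(0.2, 0.1, 0.1))
  expect_identical(static_relation(side, b, tnr = "T", big), "ArT")
  expect_identical(static_relation(side, b, tnr = "N", big), "Ar")
  # far pairs have no static relation
  far <- cube(c(10, 0, 0), c(11, 1, 1))
  expect_identical(static_relation(far, b, tnr = "N", p), "O")
  # containment wins over direction
  inner <- cube(c(0.02, 0.03, 0.02), c(0.08, 0.09, 0.08))
  expect_identical(static_relation(inner, b, tnr = "T", big), "In")
  expect_identical(static_relation(b, inner, tnr = "T", big), "Sa")
})

test_that("static relation agrees with a naive transliteration oracle", {
  set.seed(41)
  for (i in 1:300) {
    a <- random_cube(); b <- random_cube()
    tnr <- touching(a, b, p)
    expect_identical(static_relation(a, b, tnr, p),
                     naive_static(a, b, tnr, p$far_threshold),
                     info = paste(c(a, b), collapse = ","))
  }
})

test_that("swapping arguments swaps Ab/Be (and To/Bo, In/Sa) and fixes Ar/O", {
  set.seed(7)
  swaps <- c(Ab = "Be", Be = "Ab", To = "Bo", Bo = "To", In = "Sa", Sa = "In",
             Ar = "Ar", ArT = "ArT", O = "O")
  checked <- 0L
  for (i in 1:400) {
    a <- random_cube(); b <- random_cube()
    ov <- c(min(a[4], b[4]) - max(a[1], b[1]),
            min(a[5], b[5]) - max(a[2], b[2]),
            min(a[6], b[6]) - max(a[3], b[3]))
    if (all(ov > 0)) next  # interpenetration: direction is ill-defined
    tnr <- touching(a, b, p)
    ab <- static_relation(a, b, tnr, p)
    ba <- static_relation(b, a, tnr, p)
    expect_identical(ba, unname(swaps[ab]), info = paste(c(a, b), collapse = ","))
    checked <- checked + 1L
  }
  expect_gt(checked, 200L)
})

test_that("dynamic relation covers the window rules", {
  win <- function(a0, b0, va = c(0, 0, 0), vb = c(0, 0, 0), n = 11) {
    dt <- seq(0, by = 1 / 20, length.out = n)
    list(a = t(vapply(dt, function(t) a0 + rep(va * t, 2), numeric(6))),
         b = t(vapply(dt, function(t) b0 + rep(vb * t, 2), numeric(6))))
  }
  touch_a <- cube(c(0, 0.1, 0), c(0.1, 0.2, 0.1))
  touch_b <- cube(c(0, 0, 0), c(0.1, 0.1, 0.1))
  # both centres displaced together while touching
  w <- win(touch_a, touch_b, va = c(0.6, 0, 0), vb = c(0.6, 0, 0))
  expect_identical(dynamic_relation(w$a, w$b, p), "MT")
  # neither moves
  w <- win(touch_a, touch_b)
  expect_identical(dynamic_relation(w$a, w$b, p), "HT")
  # exactly one moves across the other
  w <- win(touch_a, touch_b, va = c(0.3, 0, 0))
  expect_identical(dynamic_relation(w$a, w$b, p), "FMT")
  # non-touching, distance shrinks by 0.25 m over the window
  apart <- cube(c(0.6, 0, 0), c(0.7, 0.1, 0.1))
  w <- win(apart, touch_b, va = c(-0.5, 0, 0))
  expect_identical(dynamic_relation(w$a, w$b, p), "GC")
  w <- win(apart, touch_b, va = c(0.5, 0, 0))
  expect_identical(dynamic_relation(w$a, w$b, p), "MA")
  # distance change of 2 mm is Stable
  w <- win(apart, touch_b, va = c(-0.004, 0, 0))
  expect_identical(dynamic_relation(w$a, w$b, p), "S")
  # in-between drift is Q
  w <- win(apart, touch_b, va = c(-0.1, 0, 0))
  expect_identical(dynamic_relation(w$a, w$b, p), "Q")
  # far pairs are Q regardless of motion
  faraway <- cube(c(3, 0, 0), c(3.1, 0.1, 0.1))
  w <- win(faraway, touch_b, va = c(-0.5, 0, 0))
  expect_identical(dynamic_relation(w$a, w$b, p), "Q")
  # short history is an error
  w <- win(apart, touch_b, n = 5)
  expect_error(dynamic_relation(w$a, w$b, p), "undefined-history")
})

test_that("labels are invariant under joint scaling of geometry and thresholds", {
  set.seed(11)
  for (s in c(0.1, 3, 40)) {
    ps <- relation_params(eps_touch = p$eps_touch * s,
                          xi_stable = p$xi_stable * s,
                          xi_motion = p$xi_motion * s,
                          eps_move = p$eps_move * s,
                          far_threshold = p$far_threshold * s)
    for (i in 1:60) {
      a <- random_cube(); b <- random_cube()
      tnr <- touching(a, b, p)
      expect_identical(touching(a * s, b * s, ps), tnr)
      expect_identical(static_relation(a * s, b * s, tnr, ps),
                       static_relation(a, b, tnr, p))
    }
  }
})
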