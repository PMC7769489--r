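# ten single-column eSECs whose codes we control exactly: action k flips the
# first TNR cell when listed in `odd`
ten_actions <- function(odd = integer(0), k = 1) {
  out <- lapply(1:10, function(i) {
    m <- matrix(base_column(), 30, k)
    if (k > 1) for (j in seq(2, k, 2)) m[2, j] <- "T"
    if (i %in% odd) m[1, ] <- "U"
    esec(m, action_label = paste0("a", i))
  })
  stats::setNames(out, paste0("a", 1:10))
}

test_that("self-information is -log2(p) on (0, 1]", {
  expect_equal(self_information(1), 0)
  expect_equal(self_information(0.5), 1)
  expect_equal(round(self_information(0.1), 4), 3.3219)
  expect_error(self_information(0), "domain error")
  expect_error(self_information(1.2), "domain error")
})

test_that("column codes concatenate the model's rows and flag ended actions", {
  es <- ten_actions()
  code_t <- column_code(es, "a1", 1, "T")
  expect_length(strsplit(code_t, "|", fixed = TRUE)[[1]], 10L)
  expect_length(strsplit(column_code(es, "a1", 1, "Overall"), "|",
                         fixed = TRUE)[[1]], 30L)
  expect_identical(column_code(es, "a1", 99, "T"), "ENDED")
  expect_error(column_code(es, "a1", 1, "bogus"), "domain error")
})

test_that("likelihoods follow the column-code frequency rule", {
  # all ten actions share every code
  same <- likelihood_table(ten_actions(), "T")
  expect_true(all(same$likelihood == 1))
  expect_true(all(same$info == 0))
  # one action unique, nine shared
  lt <- likelihood_table(ten_actions(odd = 4), "T")
  expect_equal(lt$likelihood[lt$action == "a4"], 0.1)
  expect_equal(lt$likelihood[lt$action != "a4"], rep(0.9, 9))
  # the sub-tables not containing the flipped row are unaffected
  lt_s <- likelihood_table(ten_actions(odd = 4), "S")
  expect_true(all(lt_s$likelihood == 1))
  expect_error(likelihood_table(ten_actions()[1], "T"), "domain error")
})

test_that("ended actions participate as a pseudo-code", {
  es <- ten_actions(k = 4)
  # seven actions stop after two columns, three continue to four
  for (i in 1:7) es[[i]] <- esec(es[[i]]$mat[, 1:2],
                                 action_label = paste0("a", i))
  lt <- likelihood_table(es, "T")
  at3 <- lt[lt$column == 3, ]
  expect_equal(at3$likelihood[at3$action %in% paste0("a", 1:7)], rep(0.7, 7))
  expect_equal(at3$likelihood[at3$action %in% paste0("a", 8:10)], rep(0.3, 3))
  expect_true(all(at3$code[1:7] == "ENDED"))
})

test_that("likelihoods are a frequency distribution over distinct codes", {
  set.seed(5)
  es <- stats::setNames(lapply(1:10, function(i)
    random_esec(sample(2:5, 1), label = paste0("a", i))), paste0("a", 1:10))
  for (model in c("T", "S", "D", "Overall")) {
    lt <- likelihood_table(es, model)
    for (j in unique(lt$column)) {
      rows <- lt[lt$column == j, ]
      counts <- table(rows$code)
      expect_equal(as.numeric(counts[rows$code]) / 10, rows$likelihood)
      # distinct codes weighted by their frequency form a distribution
      expect_equal(sum(as.vector(counts)) / 10, 1)
    }
  }
})

test_that("sum models add bits, Overall is its own model, cumulation runs", {
  set.seed(6)
  es <- stats::setNames(lapply(1:10, function(i)
    random_esec(3, label = paste0("a", i))), paste0("a", 1:10))
  info <- info_table(es)
  key <- function(m) info[info$model == m, ]
  expect_equal(key("T+S")$info, key("T")$info + key("S")$info)
  expect_equal(key("T+S+D")$info,
               key("T")$info + key("S")$info + key("D")$info)
  # cumulative information: starts at the absolute value, never decreases
  for (m in INFO_MODELS) {
    km <- key(m)
    for (a in unique(km$action)) {
      ka <- km[km$action == a, ]
      ka <- ka[order(ka$column), ]
      expect_equal(ka$cum_info[1], ka$info[1])
      expect_true(all(diff(ka$cum_info) >= -1e-12))
      expect_equal(ka$cum_info, cumsum(ka$info))
    }
  }
  expect_true(all(info$info >= 0))
  # grid mismatch is rejected
  t1 <- likelihood_table(es, "T")
  expect_error(combine_and_accumulate(list("T" = t1, "S" = t1[-1, ],
                                           "D" = t1)),
               "grid mismatch")
})

test_that("Overall can differ from T+S+D when code sharing differs", {
  # action pairs share different sub-table codes, so summed bits exceed the
  # information of the full 30-symbol code
  mk <- function(tnr1, ssr1, label) {
    m <- matrix(base_column(), 30, 1)
    m[1, 1] <- tnr1; m[11, 1] <- ssr1
    esec(m, action_label = label)
  }
  es <- list(a = mk("T", "Ab", "a"), b = mk("T", "Be", "b"),
             c = mk("N", "Ab", "c"), d = mk("N", "Be", "d"))
  info <- info_table(es)
  ov <- info$info[info$model == "Overall"]
  su <- info$info[info$model == "T+S+D"]
  # every overall code is unique (2 bits); T and S codes are each shared by
  # two actions (1 bit each), D by all (0 bits): the sum exceeds the overall
  expect_equal(ov, rep(2, 4))
  expect_equal(su, rep(2, 4))
  # with a third distinguishing row the sum double-counts
  es$b <- mk("T", "Ab", "b")  # b now equals a in T and S
  info <- info_table(es)
  expect_false(isTRUE(all.equal(info$info[info$model == "Overall"],
                                info$info[info$model == "T+S+D"])))
})
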