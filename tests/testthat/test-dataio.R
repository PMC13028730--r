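make_design_df <- function(n_per_arm = 9) {
  tt <- design_times()
  rec <- lapply(seq_len(2 * n_per_arm), function(i) {
    data.frame(ID = i, TIME = c(0, tt),
               AMT = c(0.2, rep(NA, length(tt))),
               DV = c(NA, exp(-0.05 * tt) + 0.01),
               EVID = c(1L, rep(0L, length(tt))),
               FORM = if (i <= n_per_arm) "FREE" else "NC",
               WT = 12.5, AGE = 30)
  })
  do.call(rbind, rec)
}

test_that("a full two-arm design validates and summarises correctly", {
  d <- pk_dataset(make_design_df())
  s <- summary(d)
  expect_equal(s$n_subjects, 18)
  expect_equal(unname(s$n_per_arm), c(9, 9))
  expect_equal(s$n_obs, 198)
  expect_equal(sum(d$EVID == 1), 18)
})

test_that("single-subject datasets count into exactly one arm", {
  df <- make_design_df(1)
  d1 <- pk_dataset(df[df$ID == 1, ])
  expect_equal(unname(summary(d1)$n_per_arm), c(1, 0))
  d2 <- pk_dataset(df[df$ID == 2, ])
  expect_equal(unname(summary(d2)$n_per_arm), c(0, 1))
})

test_that("structural violations are rejected with addressable messages", {
  df <- make_design_df(2)
  expect_error(pk_dataset(df[df$EVID == 0 | df$ID != 3, ]),
               "subject 3 has 0 dose events")
  df2 <- df; df2$TIME[2] <- -1
  expect_error(pk_dataset(df2), "negative")
  df3 <- df; df3$TIME[3] <- df3$TIME[2]
  expect_error(pk_dataset(df3), "duplicated observation times")
  df4 <- df; df4$DV[1] <- 1  # dose row also carrying an observation
  expect_error(pk_dataset(df4), "dose and observation")
  df5 <- df; df5$DV[2] <- 0
  expect_error(pk_dataset(df5), "strictly positive")
  expect_error(pk_dataset(df[, setdiff(names(df), "DV")]),
               "missing required column")
})

test_that("write/read round-trips a dataset exactly", {
  d <- simulate_study(sim_config(n_per_arm = 3), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_pkdata(d, path)
  d2 <- read_pkdata(path)
  expect_identical(d2$ID, d$ID)
  expect_identical(d2$EVID, d$EVID)
  expect_identical(as.character(d2$FORM), as.character(d$FORM))
  expect_equal(d2$TIME, d$TIME, tolerance = 1e-12)
  expect_equal(d2$DV, d$DV, tolerance = 1e-12)
  expect_equal(d2$AMT, d$AMT, tolerance = 1e-12)
})

test_that("an empty dataset writes a header-only file that reads back", {
  d <- pk_dataset(make_design_df()[0, ])
  path <- tempfile(fileext = ".csv")
  write_pkdata(d, path)
  lines <- readLines(path)
  expect_length(lines, 2)  # comment + header
  expect_equal(nrow(read_pkdata(path)), 0)
})

test_that("column dialects map NONMEM-style names", {
  d <- simulate_study(sim_config(n_per_arm = 2), seed = 5)
  path <- tempfile(fileext = ".csv")
  df <- as.data.frame(d)
  names(df) <- c("id", "time", "amt", "CONC", "evid", "FORM", "WT", "AGE")
  df$FORM <- as.integer(df$FORM == "NC")
  write.csv(df, path, row.names = FALSE, na = "")
  dialect <- list(ID = "id", TIME = "time", AMT = "amt", DV = "CONC",
                  EVID = "evid")
  d2 <- read_pkdata(path, dialect = dialect)
  expect_equal(d2$DV, d$DV, tolerance = 1e-12)
  expect_error(read_pkdata(path, dialect = list(DV = "nope")),
               "absent column")
})

test_that("excluded rows are dropped with a log message", {
  d <- simulate_study(sim_config(n_per_arm = 2), seed = 5)
  path <- tempfile(fileext = ".csv")
  df <- as.data.frame(d)
  df$FORM <- as.integer(df$FORM == "NC")
  df$EXCL <- 0
  df$EXCL[3] <- 1
  write.csv(df, path, row.names = FALSE, na = "")
  expect_message(d2 <- read_pkdata(path), "excluded row")
  expect_equal(sum(d2$EVID == 0), sum(d$EVID == 0) - 1)
})
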