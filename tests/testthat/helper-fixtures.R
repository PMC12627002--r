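# Hand-built three-household survey fixture in the pipeline CSV schema.
# Household 1 reproduces the documented income-construction example:
# (50000 - 1000 - 500 - 400 - 230) / 2 = 23935 per capita.
make_survey_fixture <- function() {
  blank <- function(n) rep(0, n)
  df <- data.frame(
    hid = c(1, 1, 2, 3, 3),
    pid = c(1, 2, 1, 1, 2),
    region = c("East", "East", "Central", "West", "West"),
    a2000 = c(2, 2, 1, 2, 2),
    wage_income = c(50000, 50000, 80000, 20000, 20000),
    agricultural_income = c(0, 0, 0, 6000, 6000),
    business_income = blank(5),
    property_income = blank(5),
    transfer_income = c(0, 0, 2000, 1000, 1000),
    a3137 = c(1000, 1000, 3000, 0, 0),
    is_worker = c(1, 0, 1, 1, 0),
    f2001a = c(2, 2, 1, 4, NA),
    f2004 = c(400, 0, 0, 400, 0),
    f1008 = c(0, 0, 100, 0, 0),
    f1008a = c(0, 500, 0, 0, 0),
    f2024 = c(5000, 0, 12000, 3000, 0),
    f2028 = c(0, 800, 2000, 0, 400),
    f2025_1 = c(0, 0, 8000, 0, 0),
    f2025_2 = c(2000, 0, 0, 0, 0),
    f2025_3 = blank(5),
    f2025_4 = c(0, 0, 0, 1500, 0),
    f2025_5 = blank(5),
    f2029_1 = c(0, 0, 1000, 0, 0),
    f2029_2 = c(0, 200, 0, 0, 0),
    f2029_3 = blank(5),
    f2029_4 = blank(5),
    f2029_5 = blank(5),
    stringsAsFactors = FALSE
  )
  df
}

# Absolute-tolerance comparison for values published at fixed precision.
expect_abs_equal <- function(actual, expected, tol = 5e-5) {
  expect_lt(max(abs(actual - expected)), tol)
}

# Random valid grouped-income vectors for property-style checks.
random_income_vector <- function() {
  n <- sample(2:50, 1)
  x <- stats::runif(n, 0, 10)
  if (sum(x) <= 0) x <- x + 1
  x
}
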