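# Field program construction, evaluation and presets.

test_that("rotating field phase convention and norm preservation", {
  pr <- field_rotating(4, 1, "yz")
  expect_equal(evaluate_field(pr, 0), c(0, 4, 0))
  expect_equal(evaluate_field(pr, 1 / 4), c(0, 0, 4), tolerance = 1e-12)
  ts <- seq(0, 2, length.out = 101)
  B <- evaluate_field(pr, ts)
  expect_equal(sqrt(rowSums(B^2)), rep(4, 101), tolerance = 1e-12)
})

test_that("conical field preserves norm and precesses about its axis", {
  pr <- field_conical(6, 32, axis = c(0, 0, 1), half_angle = 80 * pi / 180)
  ts <- seq(0, 0.1, length.out = 200)
  B <- evaluate_field(pr, ts)
  expect_equal(sqrt(rowSums(B^2)), rep(6, 200), tolerance = 1e-12)
  expect_equal(B[, 3], rep(6 * cos(80 * pi / 180), 200), tolerance = 1e-12)
})

test_that("oscillating field attains exactly its angular bounds", {
  bounds <- c(-2 * pi / 3, pi / 3)
  pr <- field_oscillating(6, 3, bounds)
  ts <- seq(0, 1 / 3, length.out = 20001)
  B <- evaluate_field(pr, ts)
  ang <- atan2(B %*% c(0, 0, 1), B %*% c(0, 1, 0))
  expect_equal(min(ang), bounds[1], tolerance = 1e-8)
  expect_equal(max(ang), bounds[2], tolerance = 1e-8)
})

test_that("single-segment programs are periodic with period 1/f", {
  for (pr in list(field_rotating(4, 2), field_oscillating(6, 3, c(-1, 1)),
                  field_conical(5, 8))) {
    ts <- seq(0, 0.9, length.out = 37)
    d <- evaluate_field(pr, ts) - evaluate_field(pr, ts + 1 / pr$f_Hz)
    expect_lt(max(abs(d)), 1e-12 * pr$B0_mT)
  }
})

test_that("schedules switch segments and hold the last one", {
  sched <- field_schedule(
    list(1, field_static(4, c(0, 1, 0))),
    list(1, field_static(2, c(0, 0, 1)))
  )
  expect_equal(evaluate_field(sched, 0.5), c(0, 4, 0))
  expect_equal(evaluate_field(sched, 1.5), c(0, 0, 2))
  expect_equal(evaluate_field(sched, 10), c(0, 0, 2))  # hold last
  expect_error(field_schedule(list(1, sched)), "nested")
})

test_that("field reversal negates the program at every instant", {
  pr <- field_oscillating(6, 2, c(-1, 0.5))
  rv <- field_reverse(pr)
  ts <- seq(0, 1, length.out = 31)
  expect_equal(evaluate_field(rv, ts), -evaluate_field(pr, ts))
})

test_that("presets carry the documented amplitudes and frequencies", {
  w <- field_preset("walking")
  expect_equal(w$variant, "rotating")
  expect_equal(w$B0_mT, 4)
  expect_equal(w$f_Hz, 1)
  cr <- field_preset("crawling")
  expect_equal(cr$variant, "oscillating")
  expect_equal(cr$B0_mT, 6)
  expect_equal(cr$f_Hz, 3)
  expect_equal(c(cr$a1 - cr$a2, cr$a1 + cr$a2), c(-2 * pi / 3, pi / 3))
  d20 <- field_preset("disassemble_20Hz")
  expect_equal(d20$f_Hz, 20)
  expect_equal(field_preset("walking", f_Hz = 10)$f_Hz, 10)
  expect_error(field_preset("somersault"), "unknown preset")
})

test_that("compiled field segments evaluate identically to the R path", {
  us <- unit_system()
  progs <- list(field_static(3, c(1, 1, 0)),
                field_rotating(4, 1.5, "xz", phase = 0.3),
                field_oscillating(6, 2, c(-2, 1), e1 = c(1, 0, 0),
                                  e2 = c(0, 0, 1)),
                field_conical(5, 12, axis = c(0, 1, 1)),
                field_schedule(list(0.5, field_rotating(4, 2)),
                               list(0.7, field_static(1, c(0, 0, 1)))))
  for (pr in progs) {
    segs <- janusim:::compile_field_program(pr, us)
    for (t in c(0, 0.1, 0.49, 0.51, 1.3, 2.7)) {
      b_cpp <- janusim:::cpp_field_eval(segs, t / us$tau) *
        us$field_unit * 1e3
      expect_equal(b_cpp, unname(evaluate_field(pr, t)), tolerance = 1e-9)
    }
  }
})
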