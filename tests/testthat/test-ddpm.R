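# Diffusion schedule, forward process, denoiser training and class balancing.

test_that("schedules match hand-computed cumulative products", {
  s <- make_schedule(2, 0.1, 0.2)
  expect_equal(s$betas, c(0.1, 0.2))
  expect_equal(s$alpha_bars, c(0.9, 0.72))
  s1000 <- make_schedule(1000, 1e-4, 0.02)
  expect_lt(s1000$alpha_bars[1000], 1e-4)
  expect_true(all(diff(s1000$betas) > 0))
  expect_true(all(diff(s1000$alpha_bars) < 0))
  expect_error(make_schedule(1), "at least 2")
  expect_error(make_schedule(10, 0.2, 0.1), "increase")
  # posterior-variance alternative is positive from t = 2 on
  sp <- make_schedule(50, 1e-3, 0.2, sigma = "posterior")
  expect_true(all(sp$sigma2[-1] > 0))
  expect_true(all(sp$sigma2 <= sp$betas + 1e-12))
})

test_that("the closed-form forward marginal matches N(sqrt(ab) x0, 1 - ab)", {
  sched <- make_schedule(40, 1e-3, 0.1)
  x0 <- 1.3
  t <- 25
  ab <- sched$alpha_bars[t]
  n <- 1e4
  draws <- forward_sample(rep(x0, n), t, sched, seed = 1000)
  se_mean <- sqrt(1 - ab) / sqrt(n)
  expect_lt(abs(mean(draws) - sqrt(ab) * x0), 3 * se_mean)
  se_var <- (1 - ab) * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(draws) - (1 - ab)), 3 * se_var)
})

test_that("composing the per-step transition equals the closed form in distribution", {
  sched <- make_schedule(12, 1e-3, 0.15)
  x0 <- rep(0.8, 2000)
  a <- forward_sample(x0, 12, sched, seed = 5, method = "closed_form")
  b <- forward_sample(x0, 12, sched, seed = 6, method = "chain")
  ratio <- stats::var(b) / stats::var(a)
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
  expect_lt(abs(mean(a) - mean(b)), 4 * sqrt(1 / 1000))
})

test_that("t = 1 with a tiny beta stays close to the input", {
  sched <- make_schedule(10, 1e-4, 0.02)
  x0 <- fx_hc_beats()$samples[, 1]
  x1 <- forward_sample(x0, 1, sched, seed = 2)
  expect_lt(max(abs(x1 - x0)), 5 * sqrt(sched$betas[1]))
  expect_error(forward_sample(x0, 11, sched), "out of")
})

# initial weights under the same seed (lr = 0 must leave them untouched)
with_seed_net_weights <- function(sched, hp) {
  m <- withr::with_seed(3, ddpm_denoiser(651, hp$channels, 9, 16))
  m$layers$c_in$params$W
}

test_that("denoiser training reduces the loss, is seeded, and freezes at lr 0", {
  beat <- fx_hc_beats()$samples[, 1, drop = FALSE]
  sched <- make_schedule(20, 1e-3, 0.2)
  hp <- list(steps = 120, channels = 8, batch_size = 8)
  m1 <- train_denoiser(beat, sched, hp, seed = 3)
  expect_lt(mean(utils::tail(m1$loss_trace, 20)),
            mean(utils::head(m1$loss_trace, 20)))
  m2 <- train_denoiser(beat, sched, hp, seed = 3)
  expect_identical(m1$loss_trace, m2$loss_trace)
  m0 <- train_denoiser(beat, sched, c(hp, list(lr = 0)), seed = 3)
  # frozen training: parameters untouched, no downward trend in the trace
  expect_equal(m0$net$layers$c_in$params$W,
               with_seed_net_weights(sched, hp))
  expect_gt(mean(utils::tail(m0$loss_trace, 40)),
            0.7 * mean(utils::head(m0$loss_trace, 40)))
  expect_error(train_denoiser(matrix(0, 651, 0), sched), "at least one")
})

test_that("sampling returns seeded beats of the training length", {
  beat <- fx_hc_beats()$samples[, 1, drop = FALSE]
  sched <- make_schedule(20, 1e-3, 0.2)
  mdl <- train_denoiser(beat, sched, list(steps = 60, channels = 8), seed = 4)
  s1 <- sample_ddpm(mdl, sched, 3, seed = 9)
  expect_equal(dim(s1), c(651, 3))
  expect_identical(s1, sample_ddpm(mdl, sched, 3, seed = 9))
  expect_gt(max(abs(s1 - sample_ddpm(mdl, sched, 3, seed = 10))), 0)
  expect_error(sample_ddpm(mdl, sched, 0), "positive")
})

test_that("balancing hits the plan targets without touching minority real beats", {
  withr::with_seed(5, {
    b <- beat_set(matrix(rnorm(651 * 120), 651),
                  label = rep(c("HC", "AMI"), c(100, 20)),
                  patient_id = paste0("P", rep(1:12, 10)), r_index = 251)
  })
  sched <- make_schedule(15, 1e-3, 0.2)
  mdl <- train_denoiser(b$samples[, 101:120], sched,
                        list(steps = 40, channels = 8), seed = 6)
  plan <- balance_plan(c(HC = 100, AMI = 20), targets = 50, seed = 7)
  out <- balance_dataset(b, plan, models = list(AMI = mdl), schedule = sched)
  tab <- table(out$meta$label, out$meta$source)
  expect_equal(tab["HC", "real"], 50)
  expect_equal(tab["AMI", "real"], 20)        # originals all retained
  expect_equal(tab["AMI", "synthetic"], 30)
  # the kept HC beats are a subset of the originals, never fabricated
  kept <- out$samples[, out$meta$label == "HC"]
  expect_true(all(kept %in% b$samples[, 1:100]))
  # identity plan leaves the dataset unchanged up to order
  same <- balance_dataset(b, balance_plan(c(HC = 100, AMI = 20),
                                          targets = c(HC = 100, AMI = 20)))
  expect_equal(sort(colSums(same$samples)), sort(colSums(b$samples)))
  # synthesis without a model is an error
  expect_error(balance_dataset(b, plan), "no model")
})

test_that("a scaled plan patterned on the published class counts validates", {
  full <- c(AMI = 6043, ALMI = 6286, ASMI = 6182, ASLMI = 5973, IMI = 5298,
            ILMI = 5845, IPMI = 5248, IPLMI = 5702, LMI = 5461, PMI = 4966,
            PLMI = 5787, HC = 5948)
  counts <- round(full / 100)
  plan <- balance_plan(counts)
  expect_equal(unname(plan$targets), rep(round(stats::median(counts)), 12))
  expect_setequal(names(plan$targets), rtcn_classes())
  expect_true(all(plan$action[plan$counts > plan$targets] == "downsample"))
  expect_true(all(plan$action[plan$counts < plan$targets] == "synthesize"))
})
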