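test_that("the default network matches the stated anatomy", {
  net <- fix_net()
  expect_equal(length(net$sources), 4L)
  pl <- net$nodes[net$nodes$name == "parietal.L", ]
  expect_equal(unlist(pl[, c("x", "y", "z")], use.names = FALSE),
               c(-29, -68, 49))
  expect_equal(unlist(net$nodes[net$nodes$name == "frontal.R",
                                c("x", "y", "z")], use.names = FALSE),
               c(33, 45, 28))
  expect_true(all(net$forward$to_pop %in% c("SS", "DP")))
  expect_true(all(net$forward$from_pop == "SP"))
  expect_true(all(net$backward$to_pop %in% c("SP", "II")))
  expect_true(all(net$backward$from_pop == "DP"))
  expect_equal(nrow(net$lateral), 4L)       # interhemispheric links
  # reduced single-hemisphere configuration
  net1 <- build_default_network(hemispheres = "L")
  expect_equal(length(net1$sources), 2L)
  expect_null(net1$lateral)
})

test_that("network description survives JSON round trip", {
  net <- build_default_network(include_sp_to_ss = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  net2 <- read_network(path)
  expect_equal(net2$sources, net$sources)
  expect_true(net2$include_sp_to_ss)
})

test_that("parameter partition is 15/12/8/6 over 41 labels", {
  pt <- count_parameters(fix_net())
  expect_equal(pt$total, 41L)
  expect_equal(unname(pt$sizes),
               c(15L, 12L, 8L, 6L))
  expect_equal(names(pt$sizes), c("NMDA", "AMPA", "GABAA", "OTHER"))
  expect_equal(length(Reduce(intersect, pt$sets)), 0L)
  # invariant to label permutation: membership travels with the label
  set.seed(3)
  perm <- sample(pt$total)
  pt2 <- count_parameters(pt$labels[perm])
  for (cl in names(pt$sets))
    expect_setequal(pt$labels[pt$sets[[cl]]],
                    pt$labels[perm][pt2$sets[[cl]]])
})

test_that("the assembled state equations have dimension 64", {
  eq <- assemble_state_equations(fix_net())
  expect_equal(eq$n_states, 64L)
  x <- rep(c(-60, 0.2, 0.2, 0.1), 16)
  expect_length(eq$f(x), 64L)
})

test_that("compiled vector field agrees with the population equations", {
  # dual route: reassemble the global field in R from
  # population_derivatives and the resolved coupling context
  net <- fix_net()
  rp <- resolve_params(NULL, net)
  ctx <- rp$ctx
  set.seed(11)
  x <- rep(c(-60, 0.2, 0.2, 0.1), 16) + rnorm(64, 0, 0.5)
  sidx <- function(s, p, st) (s - 1) * 16 + (p - 1) * 4 + st
  rates <- matrix(0, 4, 4)
  for (s in 1:4) for (p in 1:4)
    rates[p, s] <- presynaptic_rate(x[sidx(s, p, 1)],
                                    threshold = ctx$VR,
                                    variance = ctx$sigma^2)
  dx_r <- numeric(64)
  for (s in 1:4) for (p in 1:4) {
    u <- c(AMPA = sum(ctx$WA[p, , s] * rates[, s]),
           GABAA = sum(ctx$WG[p, , s] * rates[, s]),
           NMDA = sum(ctx$WN[p, , s] * rates[, s]))
    for (e in seq_len(nrow(ctx$edges))) {
      if (ctx$edges[e, 3] == s - 1 && ctx$edges[e, 4] == p - 1) {
        r <- ctx$edges[e, 5] + 1
        u[r] <- u[r] + ctx$ew[e] *
          rates[ctx$edges[e, 2] + 1, ctx$edges[e, 1] + 1]
      }
    }
    st <- x[sidx(s, p, 1):sidx(s, p, 4)]
    d <- population_derivatives(
      st, u,
      sp = list(kappa = setNames(ctx$kappa[s, ],
                                 c("AMPA", "GABAA", "NMDA")),
                gL = ctx$gL, VL = ctx$VL, C = ctx$C, bg = ctx$bg),
      mg = setNames(ctx$mg, c("alpha", "beta", "gamma")))
    dx_r[sidx(s, p, 1):sidx(s, p, 4)] <- d
  }
  eq <- assemble_state_equations(net)
  expect_equal(eq$f(x), dx_r, tolerance = 1e-12)
})

test_that("analytic Jacobian matches finite differences", {
  eq <- assemble_state_equations(fix_net())
  set.seed(5)
  x <- rep(c(-58, 0.3, 0.2, 0.1), 16) + rnorm(64, 0, 1)
  J <- eq$jacobian(x)
  Jfd <- fd_jacobian(eq$f, x, h = 1e-5)
  expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
})

test_that("zeroing extrinsic coupling decouples the sources", {
  k0 <- cmc_constants(w_fwd = 0, w_bwd = 0, w_lat = 0)
  eq <- assemble_state_equations(fix_net(), constants = k0)
  x <- rep(c(-60, 0.2, 0.2, 0.1), 16)
  J <- eq$jacobian(x)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    blk <- J[(i - 1) * 16 + 1:16, (j - 1) * 16 + 1:16]
    expect_equal(max(abs(blk)), 0)
  }
})

test_that("the SP->SS NMDA route exists only in the model variant", {
  x <- rep(c(-60, 0.2, 0.2, 0.1), 16)
  # entry: SS gNMDA (state 4) <- SP voltage (state 5) within source 1
  J0 <- assemble_state_equations(build_default_network())$jacobian(x)
  J1 <- assemble_state_equations(
    build_default_network(include_sp_to_ss = TRUE))$jacobian(x)
  expect_equal(J0[4, 5], 0)
  expect_gt(abs(J1[4, 5]), 0)
})

test_that("lead field and sensor projection behave structurally", {
  net <- fix_net()
  lf <- fix_lf(net)
  expect_equal(dim(lf$gain), c(21L, 4L))
  expect_equal(unname(colSums(lf$gain^2)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(lf$pop_weights[["II"]]), 0)
  # identity lead field and identity modes leave the CSD untouched
  S <- array(0i, c(4, 4, 3))
  set.seed(2)
  for (i in 1:3) {
    A <- matrix(rnorm(8), 4) + 1i * matrix(rnorm(8), 4)
    S[, , i] <- A %*% t(Conj(A))
  }
  idlf <- list(gain = diag(4), pop_weights = lf$pop_weights)
  class(idlf) <- "lead_field"
  out <- project_to_sensors(S, idlf, diag(4), freqs = 1:3)
  expect_equal(out$S, S, tolerance = 1e-12)
  # Hermitian output and rank bounded by the number of sources
  M <- fix_modes(lf)
  out2 <- project_to_sensors(S, lf, M, freqs = 1:3)
  for (i in 1:3) {
    sl <- out2$S[, , i]
    expect_equal(max(Mod(sl - t(Conj(sl)))), 0, tolerance = 1e-12)
    expect_lte(sum(svd(sl)$d > 1e-10 * max(svd(sl)$d)), 4)
  }
})

test_that("parameter vectors serialize to CSV and JSON", {
  lam <- setNames(c(-0.5, 0.25), c("kappa_NMDA.parietal.R", "mg.alpha"))
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_params(lam, path)
    expect_equal(read_params(path), lam, tolerance = 1e-12)
  }
})
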