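toy_conn <- function() {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.6; m[3, 4] <- 0.4
  m[1, 3] <- 0.1; m[1, 4] <- 0.2; m[2, 3] <- 0.3; m[2, 4] <- 0.4
  m <- m + t(m)
  as_conn(m)
}

toy_parc <- parcellation(data.frame(roi = paste0("r", 1:4),
                                    network = c("n1", "n1", "n2", "n2")))

test_that("4-node toy gives the hand-computed W, B and SyS", {
  s <- network_summary(toy_conn(), toy_parc)
  expect_equal(s$w, c(0.6, 0.4))
  expect_equal(s$b, c(0.25, 0.25))
  expect_equal(s$sys, c((0.6 - 0.25) / 0.6, (0.4 - 0.25) / 0.4))
  expect_true(all(s$sys_defined))
})

test_that("pairwise network means are symmetric", {
  pw <- pairwise_connectivity(toy_conn(), toy_parc)
  f <- function(a, b) pw$fc[pw$net_a == a & pw$net_b == b]
  expect_equal(f("n1", "n2"), 0.25)
  expect_equal(f("n1", "n2"), f("n2", "n1"))
})

test_that("summary equals exhaustive pair-loop enumeration", {
  for (seed in 101:110) {
    inst <- random_instance(seed, max_r = 10, max_t = 60)
    z <- compute_connectivity(inst$ts)
    s <- network_summary(z, inst$parc)
    ref <- oracle_net_summary(unclass(z), as.character(inst$parc$network))
    for (i in seq_len(nrow(s))) {
      nm <- as.character(s$network[i])
      expect_equal(s$w[i], unname(ref[[nm]]["w"]), tolerance = 1e-12)
      expect_equal(s$b[i], unname(ref[[nm]]["b"]), tolerance = 1e-12)
      expect_equal(s$sys[i], unname(ref[[nm]]["sys"]), tolerance = 1e-12)
    }
    pw <- pairwise_connectivity(z, inst$parc)
    for (i in seq_len(nrow(pw))) {
      expect_equal(pw$fc[i],
                   oracle_pairwise(unclass(z),
                                   as.character(inst$parc$network),
                                   pw$net_a[i], pw$net_b[i]),
                   tolerance = 1e-12)
    }
  }
})

test_that("relabelling ROIs leaves every W, B and SyS unchanged", {
  for (seed in 201:205) {
    inst <- random_instance(seed, max_r = 10, max_t = 60)
    s0 <- network_summary(compute_connectivity(inst$ts), inst$parc)
    set.seed(seed)
    perm <- sample(nrow(inst$parc))
    parc_p <- parcellation(data.frame(roi = inst$parc$roi[perm],
                                      network = inst$parc$network[perm]))
    s1 <- network_summary(compute_connectivity(inst$ts[, perm]), parc_p)
    j <- match(as.character(s0$network), as.character(s1$network))
    expect_equal(s1$w[j], s0$w, tolerance = 1e-12)
    expect_equal(s1$b[j], s0$b, tolerance = 1e-12)
    expect_equal(s1$sys[j], s0$sys, tolerance = 1e-12)
  }
})

test_that("edge perturbations move SyS in the expected direction", {
  base <- toy_conn()
  s0 <- network_summary(base, toy_parc)
  # raising a cross-network edge weakly lowers segregation of both networks
  up_cross <- unclass(base)
  up_cross[1, 3] <- up_cross[3, 1] <- up_cross[1, 3] + 0.2
  s1 <- network_summary(as_conn(up_cross), toy_parc)
  expect_lt(s1$sys[1], s0$sys[1])
  expect_lt(s1$sys[2], s0$sys[2])
  # raising a within-network edge weakly raises that network's segregation
  up_within <- unclass(base)
  up_within[1, 2] <- up_within[2, 1] <- up_within[1, 2] + 0.2
  s2 <- network_summary(as_conn(up_within), toy_parc)
  expect_gt(s2$sys[1], s0$sys[1])
})

test_that("a zero-W network is flagged, not fatal", {
  m <- matrix(0, 4, 4)
  m[3, 4] <- m[4, 3] <- 0.4
  m[1, 3] <- m[3, 1] <- 0.1
  s <- network_summary(as_conn(m), toy_parc)
  expect_false(s$sys_defined[s$network == "n1"])
  expect_true(is.na(s$sys[s$network == "n1"]))
  expect_true(s$sys_defined[s$network == "n2"])
})

test_that("system_segregation obeys its closed-form limits", {
  expect_equal(system_segregation(0.5, 0.1), 0.8)
  expect_equal(system_segregation(0.7, 0.7), 0)
  expect_equal(system_segregation(0.3, 0), 1)
  expect_error(system_segregation(0, 0.1), class = "sysseg_undefined_error")
  expect_error(system_segregation(-1, 0.1), class = "sysseg_undefined_error")
})

test_that("the supplied parcellation defines the rest of the cortex", {
  # restricting the parcellation to fewer networks changes B
  inst <- random_instance(7, max_r = 10, max_t = 80)
  full <- inst$parc
  nets <- levels(full$network)
  if (length(nets) >= 3) {
    z_full <- compute_connectivity(inst$ts)
    keep <- full$network %in% nets[1:2]
    sub <- parcellation(data.frame(roi = full$roi[keep],
                                   network = full$network[keep]))
    z_sub <- compute_connectivity(inst$ts[, keep])
    s_full <- network_summary(z_full, full)
    s_sub <- network_summary(z_sub, sub)
    b_full <- s_full$b[match(nets[1], s_full$network)]
    b_sub <- s_sub$b[match(nets[1], s_sub$network)]
    expect_false(isTRUE(all.equal(b_full, b_sub)))
  }
})

test_that("cohort_network_summary returns tidy per-subject rows", {
  inst <- random_instance(9, max_r = 8, max_t = 40)
  ts_list <- list(s1 = inst$ts, s2 = inst$ts + rnorm(length(inst$ts)))
  out <- cohort_network_summary(ts_list, inst$parc)
  expect_named(out, c("subject", "network", "w", "b", "sys"))
  expect_equal(nrow(out), 2 * nlevels(inst$parc$network))
})
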