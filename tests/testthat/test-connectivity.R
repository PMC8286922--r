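test_that("random wiring respects probability, self-edges and determinism", {
  pops <- tiny_populations()
  # p = 0: no edges for that projection
  n0 <- build_network(pops, tiny_projections(p_rr = 0, p_rf = 0.5),
                      seed = 4, param_table = param_tab)
  expect_false(any(n0$edges$proj == "CTX_RS->CTX_RS"))
  # p = 1 without self-edges: exactly m*(m-1) recurrent, m*n cross
  n1 <- build_network(pops, tiny_projections(p_rr = 1, p_rf = 1),
                      seed = 4, param_table = param_tab)
  expect_equal(sum(n1$edges$proj == "CTX_RS->CTX_RS"), 20 * 19)
  expect_equal(sum(n1$edges$proj == "CTX_FS->CTX_RS"), 10 * 20)
  expect_false(any(n1$edges$src == n1$edges$tgt &
                     n1$edges$proj == "CTX_RS->CTX_RS"))
  # same seed, same graph; different seed, different graph
  a <- build_network(pops, tiny_projections(), seed = 11,
                     param_table = param_tab)
  b <- build_network(pops, tiny_projections(), seed = 11,
                     param_table = param_tab)
  c <- build_network(pops, tiny_projections(), seed = 12,
                     param_table = param_tab)
  expect_identical(a$edges, b$edges)
  expect_false(identical(a$edges, c$edges))
})

test_that("edge signs follow the source population (Dale-like rule)", {
  net <- build_network(seed = 2)
  e <- net$edges
  pops <- bgloop:::pop_of(net)
  inhib <- c("CTX_FS", "D1_MSN", "D2_MSN", "GPe", "GPi")
  expect_true(all(e$weight[pops[e$src] %in% inhib] <= 0))
  expect_true(all(e$weight[!pops[e$src] %in% inhib] >= 0))
  # magnitudes respect the per-projection bound
  pr <- net$projections
  for (i in seq_len(nrow(pr))) {
    key <- paste(pr$source[i], pr$target[i], sep = "->")
    expect_true(all(abs(e$weight[e$proj == key]) <= pr$w_max_abs[i]))
  }
})

test_that("a mixed-sign efferent table is rejected", {
  bad <- tiny_projections()
  bad$source <- c("CTX_RS", "CTX_RS")
  bad$sign <- c(1, -1)
  tmp <- tempfile(fileext = ".tsv")
  write.table(bad, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(projection_table(tmp), "both signs")
})

test_that("synaptic_input sums delayed weighted pulses", {
  pops <- tiny_populations()
  net <- build_network(pops, tiny_projections(p_rr = 1, p_rf = 0),
                       seed = 3, param_table = param_tab)
  # no spikes in the window: zero current everywhere
  none <- synaptic_input(net, data.frame(neuron = integer(0),
                                         time_ms = numeric(0)),
                         phi = 0.5, t = 10)
  expect_equal(none, numeric(net$n_total))
  # one spike on neuron 1 arrives at t = spike + delay on its targets only
  spk <- data.frame(neuron = 1L, time_ms = 5)
  at_arrival <- synaptic_input(net, spk, phi = 0.5, t = 7) # delay 2 ms
  e1 <- net$edges[net$edges$src == 1, ]
  expect_equal(at_arrival[e1$tgt], e1$weight)
  expect_equal(sum(at_arrival != 0), nrow(e1))
  before <- synaptic_input(net, spk, phi = 0.5, t = 6)
  expect_equal(sum(before != 0), 0) # causality: nothing before the delay
  expect_error(synaptic_input(net, spk, phi = 0.5, t = 2), "precedes")
})

test_that("dopamine scales cortico-striatal input up for D1, down for D2", {
  net <- build_network(seed = 5)
  d1 <- bgloop:::pop_ids(net, "D1_MSN")
  d2 <- bgloop:::pop_ids(net, "D2_MSN")
  ctx <- bgloop:::pop_ids(net, "CTX_RS")[1:30]
  spikes <- data.frame(neuron = ctx, time_ms = 0)
  lo <- synaptic_input(net, spikes, phi = 0.5, t = 10) # ctx->MSN delay 10
  hi <- synaptic_input(net, spikes, phi = 1.0, t = 10)
  expect_gt(sum(hi[d1]), sum(lo[d1]))
  expect_lt(sum(hi[d2]), sum(lo[d2]))
  # brute-force oracle at phi = 1: edges onto D1 scaled by g1, D2 by g2
  e <- net$edges
  arr <- e[e$src %in% ctx & e$delay_ms == 10, ]
  g <- bgloop:::da_input_gains(1)
  expect_equal(sum(hi[d1]),
               g$g1 * sum(arr$weight[arr$tgt %in% d1]), tolerance = 1e-9)
  expect_equal(sum(hi[d2]),
               g$g2 * sum(arr$weight[arr$tgt %in% d2]), tolerance = 1e-9)
})

test_that("edge list round-trips through plain text", {
  net <- build_network(tiny_populations(), tiny_projections(), seed = 6,
                       param_table = param_tab)
  path <- tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$weight, net$edges$weight)
  expect_true(all(back$source_pop %in% c("CTX_RS", "CTX_FS")))
})
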