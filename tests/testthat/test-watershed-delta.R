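test_that("network construction inverts downstream links and validates input", {
  net <- toy_network()
  expect_setequal(net$upstream[["C"]], c("A", "B"))
  expect_length(net$upstream[["A"]], 0)
  expect_identical(net$outlets, "C")

  bad <- toy_records()
  bad$downstream_id[1] <- "Z"
  expect_error(build_network(bad), "does not match any node id")

  dup <- rbind(toy_records(), toy_records()[1, ])
  expect_error(build_network(dup), "duplicate")

  neg <- toy_records()
  neg$area_km2[2] <- -1
  expect_error(build_network(neg), "non-positive")

  cyc <- toy_records()
  cyc$downstream_id <- c("C", "C", "A")
  expect_error(build_network(cyc), "cycle")

  shrink <- toy_records()
  shrink$area_km2[3] <- 1.5   # below the sum of its upstream areas
  expect_error(build_network(shrink), "increment")
})

test_that("network construction is invariant to input row order", {
  net <- random_network(20, seed = 11)
  records <- net$nodes
  set.seed(99)
  shuffled <- build_network(records[sample.int(nrow(records)), ])
  expect_identical(shuffled$nodes, net$nodes)
  expect_identical(shuffled$upstream, net$upstream)
})

test_that("incremental areas accumulate to the cumulative convention", {
  rec <- toy_records()
  rec$area_km2 <- c(1, 1, 2)  # C's own increment
  net <- build_network(rec, areas = "incremental")
  expect_equal(net$nodes$area_km2[net$nodes$id == "C"], 4)
})

test_that("delta-EC reproduces the confluence arithmetic", {
  d <- delta_ec(toy_network(), "spring")
  expect_equal(d$delta_ec[match(c("A", "B", "C"), d$id)], c(5, 7, 3))
  expect_equal(d$provenance[match(c("A", "B", "C"), d$id)],
               c("headwater", "headwater", "corrected"))

  # single-node network: delta-EC is the EC itself
  one <- build_network(data.frame(id = "X", downstream_id = NA,
                                  area_km2 = 2, centroid_x = 0,
                                  centroid_y = 0, ec_s = 13.7))
  expect_equal(delta_ec(one, "s")$delta_ec, 13.7)

  expect_error(delta_ec(toy_network(), "winter"), "no EC column")
  miss <- toy_records()
  miss$ec_spring[2] <- NA
  expect_error(delta_ec(build_network(miss), "spring"), "'B'")
})

test_that("delta-EC inverts exactly on random trees (round trip)", {
  toy <- toy_network()
  ec <- invert_delta_ec(toy, c(A = 5, B = 7, C = 3))
  expect_equal(unname(ec["C"]), 6)
  expect_equal(unname(invert_delta_ec(toy, c(A = 0, B = 0, C = 0))),
               c(0, 0, 0))

  for (n in c(20, 200)) {
    net <- random_network(n, seed = n)
    set.seed(n + 1)
    delta <- stats::setNames(stats::runif(n, 0, 10), net$nodes$id)
    net$nodes$ec_s <- as.numeric(invert_delta_ec(net, delta)[net$nodes$id])
    back <- delta_ec(net, "s")
    expect_lt(max(abs(back$delta_ec - delta[back$id])), 1e-9)
  }
})

test_that("area-weighted delta-EC telescopes to the outlet load", {
  d <- delta_ec(toy_network(), "spring")
  expect_equal(sum(d$delta_ec * c(1, 1, 4)[match(d$id, c("A", "B", "C"))]),
               6 * 4)

  net <- random_network(54, seed = 3)
  set.seed(4)
  net$nodes$ec_s <- stats::runif(54, 5, 30)
  d <- delta_ec(net, "s")
  area <- stats::setNames(net$nodes$area_km2, net$nodes$id)
  outlet <- net$outlets
  expect_equal(sum(d$delta_ec * area[d$id]),
               net$nodes$ec_s[net$nodes$id == outlet] * area[[outlet]])
})

test_that("constant EC gives non-negative corrected values", {
  net <- random_network(30, seed = 5)
  net$nodes$ec_s <- 12
  d <- delta_ec(net, "s")
  expect_true(all(d$delta_ec >= -1e-12))
  expect_true(all(d$delta_ec[d$provenance == "headwater"] == 12))
})

test_that("exclusions drop observations but EC still feeds downstream", {
  net <- random_network(54, seed = 6)
  set.seed(7)
  net$nodes$ec_s <- stats::runif(54, 5, 30)
  ex <- exclude_nodes(net, net$nodes$id[1:2])
  expect_length(observation_ids(ex, "s"), 52)
  expect_identical(exclude_nodes(net, character(0))$nodes, net$nodes)
  expect_error(exclude_nodes(net, "nope"), "unknown node id")

  # 5-node chain: W1 <- W2 <- ... <- W5 (W1 the outlet)
  chain <- build_network(data.frame(
    id = paste0("W", 1:5),
    downstream_id = c(NA, paste0("W", 1:4)),
    area_km2 = 5:1, centroid_x = 1:5 * 1000, centroid_y = 0,
    ec_s = c(10, 9, 8, 7, 6), stringsAsFactors = FALSE
  ))
  # excluded interior node with EC: downstream correction unchanged
  with_ec <- exclude_nodes(chain, "W3")
  d <- delta_ec(with_ec, "s")
  expect_false("W3" %in% d$id)
  expect_equal(d$delta_ec[d$id == "W2"], 9 - 8 * 3 / 4)
  # excluded interior node without EC: downstream flagged unavailable
  no_ec <- with_ec
  no_ec$nodes$ec_s[no_ec$nodes$id == "W3"] <- NA
  d2 <- delta_ec(no_ec, "s")
  expect_equal(d2$provenance[d2$id == "W2"], "unavailable")
  expect_true(is.na(d2$delta_ec[d2$id == "W2"]))
  expect_length(observation_ids(no_ec, "s"), 3)
})
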