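test_that("Gabriel graph handles collinear, equilateral and obtuse cases", {
  # collinear: the middle point sits exactly on the 1-3 diametral sphere
  col3 <- landmark_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(edge_key_set(gabriel_graph(col3)$edges), c("1 2", "2 3"))
  # equilateral: opposite vertex lies outside every diametral ball
  eq <- landmark_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
  expect_equal(edge_key_set(gabriel_graph(eq)$edges), c("1 2", "1 3", "2 3"))
  # obtuse: vertex 3 witnesses against the long edge 1-2 (2 + 10 < 16)
  ob <- landmark_cloud(rbind(c(0, 0, 0), c(4, 0, 0), c(1, 1, 0)))
  expect_equal(edge_key_set(gabriel_graph(ob)$edges), c("1 3", "2 3"))
})

test_that("Gabriel graph equals the brute-force oracle on random clouds", {
  for (seed in 1:20) {
    cl <- random_cloud(30, seed)
    expect_equal(edge_key_set(gabriel_graph(cl)$edges),
                 edge_key_set(gabriel_oracle(cl$points)),
                 info = paste("seed", seed))
  }
})

test_that("Gabriel graph contains the Euclidean minimum spanning tree", {
  skip_if_not_installed("igraph")
  for (seed in c(3, 17)) {
    cl <- random_cloud(40, seed)
    d <- as.matrix(dist(cl$points))
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    mst_edges <- igraph::as_edgelist(mst)
    expect_true(all(edge_key_set(mst_edges) %in%
                    edge_key_set(gabriel_graph(cl)$edges)))
  }
})

test_that("Gabriel graph rejects degenerate inputs", {
  expect_error(gabriel_graph(landmark_cloud(matrix(1:3, 1, 3))), "at least 2")
  dup <- landmark_cloud(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)))
  expect_error(gabriel_graph(dup), "duplicate")
})

test_that("consistent adjacencies are the exact edge-set intersection", {
  g1 <- adjacency_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  g2 <- adjacency_graph(c("A", "B", "C"),
                        rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_equal(edge_key_set(consistent_adjacencies(list(g1, g2, g1))$edges),
               c("A B", "B C"))
  expect_equal(consistent_adjacencies(list(g2))$edges, g2$edges)
  g3 <- adjacency_graph(c("C", "D"), rbind(c("C", "D")))
  expect_equal(nrow(consistent_adjacencies(list(g1, g3))$edges), 0)
  expect_error(consistent_adjacencies(list()), "at least one")
})

test_that("consistency profile frequencies are correct and frequency-1 set
           reproduces the consistent set", {
  g1 <- adjacency_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  g2 <- adjacency_graph(c("A", "B", "C"),
                        rbind(c("A", "B"), c("A", "C")))
  g3 <- adjacency_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  prof <- consistency_profile(list(g1, g2, g3))
  expect_equal(prof$frequency[prof$idA == "A" & prof$idB == "B"], 1)
  expect_equal(prof$frequency[prof$idA == "A" & prof$idB == "C"], 1 / 3)
  expect_true(all(prof$frequency > 0 & prof$frequency <= 1))
  ones <- prof[prof$frequency == 1, ]
  expect_equal(sort(paste(ones$idA, ones$idB)),
               edge_key_set(consistent_adjacencies(list(g1, g2, g3))$edges))
  # property: holds on random graph ensembles too
  for (seed in 1:5) {
    graphs <- lapply(1:3, function(i)
      gabriel_graph(random_cloud(15, seed * 10 + i, named = TRUE)))
    prof <- consistency_profile(graphs)
    ones <- prof[prof$frequency == 1, ]
    expect_equal(sort(paste(ones$idA, ones$idB)),
                 edge_key_set(consistent_adjacencies(graphs)$edges))
  }
})

test_that("inconsistent-landmark compilation filters by centered window and
           orders divisions before deaths", {
  evs <- list(lineage_event("death", "zz", time = 318),
              lineage_event("division", "m", c("ma", "mp"), 318),
              lineage_event("death", "aa", time = 322),
              lineage_event("division", "b", c("ba", "bp"), 326),
              lineage_event("death", "q", time = 300),
              lineage_event("division", "x", c("xa", "xp"), 340))
  out <- compile_inconsistent(evs, stage_time = 320, window = 13)
  expect_equal(vapply(out, `[[`, "", "subject"), c("b", "m", "aa", "zz"))
  expect_equal(vapply(out, `[[`, "", "kind"),
               c("division", "division", "death", "death"))
  expect_error(compile_inconsistent(evs, 320, 0), "positive")
})

test_that("violation scoring charges missing consistent edges to both
           endpoints", {
  cons <- adjacency_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  ug <- adjacency_graph(as.character(1:3), rbind(c("1", "2")))
  # u1->A, u2->B, u3->C: A-B satisfied, B-C missing
  vs <- score_assignment(c("A", "B", "C"), cons, ug)
  expect_equal(vs$total, 1L)
  expect_equal(vs$per_identity[["B"]], 1L)
  expect_equal(vs$per_identity[["C"]], 1L)
  expect_false("A" %in% names(vs$per_identity))
  expect_equal(sum(vs$per_identity), 2L * vs$total)
  # perfect mirror: zero violations
  ug2 <- adjacency_graph(as.character(1:3), rbind(c("1", "2"), c("2", "3")))
  expect_equal(score_assignment(c("A", "B", "C"), cons, ug2)$total, 0L)
  # unassigned identity counts as missing
  vs3 <- score_assignment(c(NA, "B", "C"), cons, ug2)
  expect_equal(vs3$total, 1L)
  expect_equal(vs3$per_identity[["A"]], 1L)
  expect_equal(vs3$per_identity[["B"]], 1L)
})

test_that("violation total is invariant under unlabeled index relabeling", {
  set.seed(99)
  cl <- random_cloud(25, 1, named = TRUE)
  ug_cl <- random_cloud(25, 2)
  cons <- gabriel_graph(cl)
  mapping <- sample(cl$names)
  adj <- embalign:::gabriel_adjacency_matrix(ug_cl$points)
  base <- score_assignment(mapping, cons, adj)
  for (rep in 1:5) {
    perm <- sample(25)
    vs <- score_assignment(mapping[perm], cons, adj[perm, perm])
    expect_equal(vs$total, base$total)
  }
})

test_that("duplicate assigned identities satisfy an edge if any pair is
           adjacent", {
  cons <- adjacency_graph(c("A", "B"), rbind(c("A", "B")))
  adj <- matrix(FALSE, 3, 3)
  adj[2, 3] <- adj[3, 2] <- TRUE
  # A assigned to u1 (not adjacent to B) and u2 (adjacent): satisfied
  expect_equal(embalign:::score_mapping(
    c("A", "A", "B"), embalign:::compile_edge_struct(cons$edges), adj)$total, 0L)
  adj2 <- matrix(FALSE, 3, 3)
  expect_equal(embalign:::score_mapping(
    c("A", "A", "B"), embalign:::compile_edge_struct(cons$edges), adj2)$total, 1L)
})
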