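test_that("time trees parse with correct node ages; bad trees error", {
  tr <- read_time_tree("((Lp:3,Gc:3)crown:6.5,(Is:5,Vp:5)out:4.5)root;")
  expect_equal(tr$root_age, 9.5)
  crown <- match("crown", tr$labels)
  expect_equal(unname(tr$ages[crown]), 3)
  expect_equal(unname(tr$ages[tr$root]), 9.5)
  expect_true(all(tr$ages[1:4] == 0))

  # single tip: trivial tree
  expect_equal(read_time_tree("A;")$root_age, 0)

  # non-ultrametric beyond tolerance
  expect_error(read_time_tree("((A:1,B:2):1,C:3);"), class = "ps_tree_error")
  # duplicate tips
  expect_error(read_time_tree("((A:1,A:1):1,C:2);"), class = "ps_tree_error")
  # no branch lengths
  expect_error(read_time_tree("((A,B),C);"), class = "ps_tree_error")
})

test_that("identical lesions merge across taxa; keys separate alleles", {
  reps <- tas1r_fixture_reports()
  groups <- group_shared_lesions(reps)
  expect_equal(nrow(groups), 6L)
  shared <- groups[groups$n_carriers == 2L, ]
  expect_equal(nrow(shared), 2L)
  expect_true(all(shared$klass == "frameshift_insertion"))
  expect_true(all(vapply(shared$carriers, function(cc)
    setequal(cc, c("Lyncodon_patagonicus", "Galictis_cuja")), logical(1))))
  expect_equal(sum(groups$n_carriers == 1L), 4L)
  # reference taxa register as sampled
  expect_true("Vormela_peregusna" %in%
                attr(groups, "sampled_by_gene")$TAS1R1)

  # order invariance
  groups_rev <- group_shared_lesions(rev(reps))
  expect_equal(groups_rev$key, groups$key)
  expect_equal(groups_rev$carriers, groups$carriers)

  # same site, different allele -> distinct groups
  r1 <- reps[["Lyncodon_patagonicus.TAS1R3"]]
  r2 <- r1; r2$taxon <- "Galictis_cuja"; r2$records$taxon <- "Galictis_cuja"
  r2$records$alt <- "A"; r2$records$stop_triplet <- "TAA"
  g2 <- group_shared_lesions(list(r1, r2))
  expect_equal(nrow(g2), 2L)
  expect_true(all(g2$n_carriers == 1L))
})

test_that("Dollo origin assignment: clades, singletons, homoplasy", {
  tree <- read_time_tree("((A:1,B:1)ab:1,C:2)r;")
  # full sampled clade -> stem branch
  asg <- assign_origin_branches(
    fake_groups(list(c("A", "B")), sampled = c("A", "B", "C")), tree)
  expect_equal(asg$groups[[1]]$n_origins, 1L)
  expect_equal(asg$groups[[1]]$branches[[1]][["child"]], "ab")
  expect_false(asg$groups[[1]]$homoplasy)
  # singleton -> terminal branch
  asg <- assign_origin_branches(
    fake_groups(list("A"), sampled = c("A", "B", "C")), tree)
  expect_equal(asg$groups[[1]]$branches[[1]][["child"]], "A")
  # non-clade carriers {A, C} -> two origins, homoplasy flagged
  asg <- assign_origin_branches(
    fake_groups(list(c("A", "C")), sampled = c("A", "B", "C")), tree)
  expect_equal(asg$groups[[1]]$n_origins, 2L)
  expect_true(asg$groups[[1]]$homoplasy)
  # carriers must be tree tips
  expect_error(assign_origin_branches(fake_groups(list("ZZ")), tree),
               class = "ps_label_error")
  # unsampled tips do not contradict a clade: carriers {A} with B unsampled
  asg <- assign_origin_branches(fake_groups(list("A"), sampled = c("A", "C")),
                                tree)
  expect_equal(asg$groups[[1]]$branches[[1]][["child"]], "ab")
})

test_that("loss events bracket the origin branch in time", {
  tree <- read_time_tree("((A:1,B:1)ab:1,C:2)r;")
  st <- list(A = "pseudogene", B = "pseudogene", C = "intact")
  asg <- assign_origin_branches(
    fake_groups(list(c("A", "B")), sampled = c("A", "B", "C")), tree)
  ev <- date_gene_loss(asg, list(g = unlist(st)))
  expect_length(ev, 1L)
  expect_equal(unname(ev[[1]]$branch), c("r", "ab"))
  expect_equal(unname(ev[[1]]$interval), c(1, 2))

  # terminal-branch loss: interval [0, branch start]
  tree2 <- read_time_tree("(A:2,B:2)r;")
  asg2 <- assign_origin_branches(
    fake_groups(list("A"), sampled = c("A", "B")), tree2)
  ev2 <- date_gene_loss(asg2, list(g = c(A = "pseudogene", B = "intact")))
  expect_equal(unname(ev2[[1]]$interval), c(0, 2))

  # homoplasy: two independent origins -> two events
  tree3 <- read_time_tree("((A:1,B:1)ab:1,C:2)r;")
  asg3 <- assign_origin_branches(
    fake_groups(list(c("A", "C")), sampled = c("A", "B", "C")), tree3)
  ev3 <- date_gene_loss(asg3, list(g = c(A = "pseudogene", B = "intact",
                                         C = "pseudogene")))
  expect_length(ev3, 2L)
  expect_setequal(vapply(ev3, function(e) e$branch[["child"]], character(1)),
                  c("A", "C"))

  # no inactivating groups -> no events
  g0 <- fake_groups(list("A"), sampled = c("A", "B"))
  g0$inactivating <- FALSE
  expect_length(date_gene_loss(assign_origin_branches(g0, tree2),
                               list(g = c(A = "intact", B = "intact"))), 0L)

  # intervals always inside [0, root age]
  expect_true(ev[[1]]$interval[1] >= 0 &&
                ev[[1]]$interval[2] <= tree$root_age)
})

test_that("descendants of the loss branch are predicted pseudogenes", {
  tree <- ictonychinae_tree()
  reps <- tas1r_fixture_reports()
  asg <- assign_origin_branches(group_shared_lesions(reps), tree)
  ev <- date_gene_loss(asg, lapply(reps, call_gene_status))
  tas1r1 <- ev[[which(vapply(ev, `[[`, character(1), "gene") == "TAS1R1")]]
  expect_equal(predict_unsampled_status(tas1r1, "Galictis_vittata"),
               "pseudogene")
  expect_true(is.na(predict_unsampled_status(tas1r1, "Ictonyx_striatus")))
  expect_error(predict_unsampled_status(tas1r1, "Mustela_nivalis"),
               class = "ps_label_error")
  expect_true("Galictis_vittata" %in% tas1r1$predicted_unsampled)
})

test_that("origin counts equal exhaustive minima and never move rootward with denser sampling", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (n in 3:5) {
    trees <- phangorn::allTrees(n, rooted = TRUE, tip.label = letters[1:n])
    for (ti in seq_along(trees)) {
      phy <- trees[[ti]]          # [[ restores compressed tip labels
      tt <- ultrametricize(phy)
      subsets <- lapply(seq_len(2^n - 1), function(m)
        letters[1:n][bitwAnd(m, 2^(0:(n - 1))) > 0])
      asg <- assign_origin_branches(
        fake_groups(subsets, sampled = letters[1:n]), tt)
      got <- vapply(asg$groups, `[[`, integer(1), "n_origins")
      want <- vapply(subsets, function(cc) oracle_min_origins(phy, cc),
                     integer(1))
      expect_equal(got, want)
    }
  }

  # refinement monotonicity: sampling a carrier inside the carried clade
  # never moves the origin rootward
  tree <- read_time_tree("(((A:1,B:1)ab:1,C:2)abc:1,D:3)r;")
  sparse <- assign_origin_branches(
    fake_groups(list(c("A", "C")), sampled = c("A", "C", "D")), tree)
  dense <- assign_origin_branches(
    fake_groups(list(c("A", "B", "C")), sampled = c("A", "B", "C", "D")),
    tree)
  expect_equal(sparse$groups[[1]]$branches[[1]][["child"]], "abc")
  expect_equal(dense$groups[[1]]$branches[[1]][["child"]], "abc")
  shrunk <- assign_origin_branches(
    fake_groups(list(c("A", "C")), sampled = c("A", "B", "C", "D")), tree)
  expect_equal(shrunk$groups[[1]]$n_origins, 2L)
})
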