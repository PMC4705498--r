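# ahpneeds

Analytic Hierarchy Process (AHP) pipelines for eliciting and prioritizing
the user needs of a health technology — built around the decision tree
developed for telehealth systems that monitor, assess and help manage
Parkinson's disease (5 categories, 17 needs), and usable with any
hierarchy written in its YAML/JSON schema.

The package is aimed at researchers and developers running expert-panel
prioritization studies: it generates the pairwise questionnaire, assembles
each respondent's reciprocal judgment matrix on the integer 1–9 scale,
derives priority vectors, screens inconsistency, aggregates the panel,
quantifies consensus, compares expert subgroups, and scores a candidate
system against the resulting priorities. A synthetic panel generator makes
every stage testable without access to raw judgment data.

## The model in brief

For each comparison node, a respondent's judgments form a positive
reciprocal matrix $A$ ($a_{ii}=1$, $a_{ji}=1/a_{ij}$, entries in
$\{1/9,\dots,1/2,1,2,\dots,9\}$). The priority vector $w$ is the principal
right eigenvector of $A$ (power iteration; row geometric mean available as
a cross-check), and inconsistency is screened with

$$CI = \frac{\lambda_{\max}-n}{n-1},\qquad CR = CI / RI(n) \le 0.10,$$

using Saaty's classical random-index table. Local weights (LW) multiply
down the tree into category weights (CW) and global weights
(GW = CW × LW). Panels are consolidated by the entry-wise geometric mean
of judgments (AIJ); subgroups are summarized by element-wise median
priorities (AIP). Group consensus is an entropy-based homogeneity index
$S = (M - e^{H_\beta})/(M-1) \in [0,1]$ built from alpha/beta/gamma Shannon
diversity of the respondents' priority vectors. Subgroups are compared with
Welch t-tests per need/category and tie-corrected Spearman rank
correlation; a candidate system is scored as $\sum_i f_i\,GW_i$ from
per-need fulfillments $f_i \in [0,1]$.

See `vignettes/ahp-user-needs.Rmd` for the full account of the model,
conventions and design choices.

## Worked example

Rank the published consolidated global weights of the 17 PD telehealth
needs, then evaluate a hypothetical monitoring system against them:

```r
library(ahpneeds)

ref <- pd_reference_weights()
gw  <- setNames(ref$needs$gw_group, ref$needs$need_id)
head(rank_needs(gw), 3)
#>                               need weight rank
#> 1  increase_wearability_acceptance  0.102    1
#> 2 increase_self_management_support  0.093    2
#> 3    on_off_fluctuations_detection  0.085    3

f <- setNames(rep(1, 17), names(gw))            # system fulfills everything...
f[c("increase_patient_carers_knowledge",        # ...except patient/carer education,
    "increase_assist_care_givers",              #    caregiver support,
    "cognitive_behavioral_assessment")] <- 0    #    and non-motor assessment
f["increase_self_management_support"] <- 0.5    # self-management only partial
weighted_score(f, gw / sum(gw))
#> Weighted system evaluation: score 0.761 (residual 0.239)
#> Leading gaps:
#>                                need fulfillment    gw residual
#> 1 increase_patient_carers_knowledge         0.0 0.080   0.0800
#> 2       increase_assist_care_givers         0.0 0.070   0.0700
#> 3  increase_self_management_support         0.5 0.093   0.0465
#> 4   cognitive_behavioral_assessment         0.0 0.042   0.0420
#> 5   increase_wearability_acceptance         1.0 0.102   0.0000
```

The score says the system captures 76% of the importance-weighted needs;
the gap list says patient/carer education and caregiver support are where
the remaining weight sits — the improvement areas.

A full pipeline run on simulated judgments:

```r
sim <- simulate_judgments(paper_shaped_panel(seed = 42))   # 10 technical + 6 clinical
pr  <- analyze_panel(pd_fixture(), sim$judgments, sim$panel)
compare_groups(pr)$spearman      # rho = 0.941 between subgroup median GWs
consensus_report(pr)             # entropy-based consensus per category + overall
```

A thin command-line front end over the same functions ships in
`inst/cli/ahp-needs.R` (subcommands `questionnaire`, `simulate`,
`prioritize`, `report`, `consensus`, `compare`, `evaluate`).

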