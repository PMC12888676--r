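# Design parameters of the two published birth-cohort case studies used
# throughout the package examples. All values are taken from the running
# text of the source publications' summaries; each field carries a `source`
# note saying where the number comes from. Where a study reported an ICC and
# a total ln-scale variance instead of variance components, the components
# are derived at load time treating the total as the between-person variance
# (a best-case reading: highest power, lowest bias); see the package
# vignette.
sol_bisphenols:
  label: "Sol et al. 2020: urinary bisphenols and fetal growth"
  parameterization: components
  sigma2_between: 0.21
  sigma2_within: 0.72
  n_actual: 1379
  m_actual: 2
  sigma2_outcome: 1.0
  beta_design: 0.25
  icc_design: [0.2, 0.3]
  effects_reported:
    - value: 0.18
      scale: "SD of fetal head circumference per IQR of ln BP-S, m = 2"
    - value: -0.12
      scale: "SD of fetal head circumference per IQR of ln BP-A, m = 3"
  source:
    cohort: "1,379 pregnancies; urine sampled up to once per trimester, m = 2 for the bisphenol-S analysis carrying the strongest reported effect"
    variance_components: "ln-scale between/within-person variances of urinary bisphenol-A (0.21 / 0.72) from published repeated-measures data, assumed to carry over to bisphenol-S"
    sigma2_outcome: "outcome is a z-score of fetal growth standardized for sex and gestational age, hence unit variance"
    beta_design: "design slope fixed at one quarter of an outcome SD per ln(exposure) unit, stronger than any reported effect"
    icc_design: "reliability calculator run at ICC 0.2 and 0.3, bracketing the component-implied 0.23"
guo_triclosan_mothers:
  label: "Guo et al. 2020: maternal urinary triclosan and child motor function (boys)"
  parameterization: icc_total
  icc: 0.6
  total_variance: 0.019
  total_is_between: true
  n_actual: 377
  m_actual: 1
  sigma2_outcome: 6.0
  beta_design: 0.25
  icc_design: [0.6]
  effects_reported:
    - value: 0.25
      scale: "motor-function score per ln(maternal urinary triclosan), m = 1"
  source:
    cohort: "377 mother-child pairs; one spot urine sample per mother on delivery day"
    icc: "pregnancy urinary triclosan ICC fixed at 0.6, the top of the range the study's literature review supports (best case)"
    total_variance: "total ln-scale variance 0.019 estimated from the reported 95% CI of maternal urinary measurements; treated as between-person variance (best case)"
    sigma2_outcome: "neurodevelopment scores reported with standard deviation 6 in a companion publication; stored as a variance of 6 per the calculator-input convention"
    beta_design: "design slope equals the reported maternal-exposure slope"
guo_triclosan_boys:
  label: "Guo et al. 2020: child urinary triclosan and social development (boys)"
  parameterization: icc_total
  icc: 0.4
  total_variance: 0.0095
  total_is_between: true
  n_actual: 184
  m_actual: 1
  sigma2_outcome: 6.0
  beta_design: -0.37
  icc_design: [0.4]
  effects_reported:
    - value: -0.37
      scale: "social-development score per ln(child urinary triclosan at age 3), m = 1"
  source:
    cohort: "associations confined to the 184 boys; one spot urine sample per child around age 3"
    icc: "child urinary triclosan ICC fixed at 0.4, the top of the expected 0.2-0.4 range for children (best case)"
    total_variance: "total ln-scale variance 0.0095 estimated from the reported 95% CI of the boys' urinary measurements; treated as between-person variance (best case)"
    sigma2_outcome: "same outcome-scale convention as the maternal analysis"
    beta_design: "design slope equals the reported child-exposure slope"
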