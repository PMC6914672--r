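---
title: "Simulating daily activity patterns with needs-based agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating daily activity patterns with needs-based agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needsim)
```

## The model

`needsim` simulates a single working adult whose behavior emerges from four
competing needs — Rest, Hunger, Income, and Travel — rather than from a
fixed timetable. Each need carries a satiation $n(t) \in [0, 1]$ and a
threshold $\lambda$; the agent ignores a need until its satiation falls to
the threshold, then seeks an activity that restores it.

Two satiation dynamics are modeled:

* **Linear needs** (Rest, served by sleeping; Hunger, served by the three
  meals) decay at the constant rate
  $m_\mathrm{decay} = -(1-\lambda)/\Delta t_\mathrm{decay}$, where
  $\Delta t_\mathrm{decay}$ is the time from full satiation to the
  threshold. During the satisfying activity, satiation recovers at
  $m_\mathrm{recover} = (1-\lambda)/\Delta t_\mathrm{recover}$, and the
  realized duration is $\Delta t_\mathrm{activity} = (1-n)/m_\mathrm{recover}$,
  so an agent starting below threshold runs the activity longer than its
  minimum recovery time and always finishes fully sated. The framework
  admits any monotonically decreasing decay; only the constant-rate form is
  implemented, though `need()` carries a `kind` field so other forms can be
  added without changing the engine's interface.
* **Step needs** (Income, served by working; Travel, served by the two
  commutes) represent scheduled commitments: satiation is 1 before a clock
  trigger $t_0$ and drops to $\eta$ ($0 \le \eta \le \lambda$) at $t_0$;
  completing the activity returns it to 1 and schedules the next trigger.

Activities are offered to the agent by objects: when a need is at or below
threshold, each co-located object advertises its matching activities with a
promised satiation change $\delta$, scored by urgency,
$S(n) = W(n) - W(n + \delta)$ with $W(n) = 1/(n + \epsilon)$ below
threshold and 0 above. The agent performs the highest-scoring positive
advertisement, or idles. A no-op scores zero and a harmful offer scores
negative; the future-state term uses the continuous kernel
$1/(n + \epsilon)$ rather than the thresholded weight so that these sign
properties hold identically — for the full-recovery advertisements the
model actually issues, the two conventions differ only by a constant and
never change the ranking.

## Decision loop and schedule mechanics

The engine advances one minute per tick. Sleeping, eating, and commuting
are uninterruptible; work may be interrupted, and only by lunch, after
which work resumes until its sampled end time. Ties in score are broken by
a fixed need priority (Travel > Income > Rest > Hunger), then by activity
id; with the default parameters scores are never exactly tied, so this
choice is unobservable in practice.

Several schedule rules connect the sampled parameters to the needs:

* **Meals** are parameterized by start and duration. At a meal's end the
  next occurrence is sampled for the following day and Hunger's decay is
  re-aimed so that it reaches $\lambda$ exactly at whichever meal comes
  next. Pinning the next occurrence to the following day (rather than "the
  next future instant of the sampled clock time") prevents a meal from
  recurring twice in one day when the newly sampled start falls just after
  the realized end of the episode just eaten.
* **Sleep** is parameterized by start and end; its minimum recovery time is
  their difference. At wake, the next night's start and end are sampled and
  Rest's decay is aimed at the sampled start, which is therefore the next
  sleep trigger.
* **Work** is parameterized by start and end. Income triggers at the
  sampled start on workdays (Monday–Friday, fixed). Work is end-anchored:
  it begins when the agent arrives (the morning commute ends) and always
  ends at the sampled end time, so oversleeping shortens the workday.
* **Commutes** are parameterized by duration only and are linked to work:
  the morning Travel trigger is the sampled work start minus the sampled
  commute duration, so an on-time agent arrives exactly at the work start,
  while a late riser commutes immediately on waking; the evening trigger is
  the work end itself, so the commute home starts the minute work ends.
* **Breakfast skipping** emerges rather than being scripted: Travel's
  $\eta$ is 0 while a just-triggered Hunger sits near $\lambda = 0.2$, so
  the commute's score ($\approx 1/\epsilon$) dwarfs breakfast's
  ($\approx 1/\lambda$). An agent waking at or after the commute urge
  therefore leaves immediately; since breakfast is only available in the
  residence, it stays skipped until lunch, and the missed occurrence rolls
  to the next day.

Movement is implicit in the commutes: the agent steps outdoors when a
commute starts and into the destination when it ends (the residence and
workplace are never adjacent). While idle the agent stays wherever it last
was; transport is considered reachable from the residence and the
workplace, since performing a commute begins by stepping outside.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| $\lambda$ | 0.2 | threshold satiation, shared by all needs |
| $\epsilon$ | $10^{-9}$ | weight regularizer; any value small against the smallest satiation of interest preserves the priority ordering |
| $\eta$ (Travel) | 0.0 | post-trigger satiation; very low so commuting outranks breakfast |
| $\eta$ (Income) | 0.1 | post-trigger satiation; work outranks meals but not commuting |
| activity $\mu, \sigma$ | see `default_params()` | long-term mean and day-to-day spread of each start/end/duration, in hours |

Each parameterized quantity is drawn from $\mathcal N(\mu, \sigma)$
truncated to $[\mu - \sigma, \mu + \sigma]$ (inverse-CDF sampling), so all
draws stay within one standard deviation of the mean and the sample mean
equals $\mu$ by symmetry. The default table encodes the week of a working
adult: sleep 22:00–8:00 (wake spread $\sigma = 2.5$ h is deliberately
large, to exercise the morning competition between needs), breakfast 8:15
for 15 min, a 30-min commute to a 9:00–17:00 workday with lunch around
noon, a 60-min commute home, and dinner around 19:00 for 45 min.

```{r}
cfg <- sim_config(seed = 1)
cfg
```

## Numerical choices

* Time is integer minutes. Sampled decimal hours are rounded to the
  nearest whole minute (ties up) where they enter the clock; sub-minute
  precision is meaningless under a 1-minute tick. Realized durations from
  $\Delta t_\mathrm{activity}$ are rounded the same way and floored at one
  minute.
* Linear satiations are evaluated in closed form from their last anchor
  (value 1 at the end of the satisfying episode, constant rate), not by
  per-tick accumulation. Accumulating $10^3$ per-tick increments drifts by
  enough ($\sim 10^{-13}$) to miss an exact threshold comparison and
  displace a trigger by a minute; the closed form lands within an ulp, and
  values within $10^{-9}$ of $\lambda$ snap to it before scoring.
* Satiation is clamped to $[0, 1]$. The floor matters only when a need
  stays unsatisfied past its aim point (a skipped breakfast); the model
  states the range but no overshoot rule, and clamping is this package's
  choice.
* Day boundaries are midnight; an episode spanning midnight belongs to the
  day it started. Durations are exact elapsed minutes.
* A work occurrence whose end time passes before the agent ever arrives
  lapses (satiation restored, next occurrence scheduled); this cannot occur
  under the default parameters but keeps degenerate configurations from
  deadlocking.

## Initialization

The simulation starts with every satiation at 1 and samples the first
occurrence of each activity in a fixed documented order (sleep, breakfast,
lunch, dinner, work, commute to work, commute from work), consuming a
single seeded random stream; zero-variance parameters consume no draws.
The default horizon is 7 days plus an 8-hour warm-up evening beginning
Sunday 16:00: the warm-up exists so the first night's sleep is scheduled
through the same trigger mechanism as every later one (Rest's decay is
aimed from the start time at the sampled bedtime). Runs are deterministic
given the seed.

## Verification design

Two independent routes compute the same schedule. `run_simulation()` walks
the decision loop minute by minute; `oracle_schedule()` builds the diary of
any zero-variance configuration by pure event arithmetic (triggers at the
means, durations equal to the minimum recovery times, links enforced by
construction) and refuses anything stochastic or mis-ordered. The test
suite requires the two to agree minute-for-minute across a battery of
zero-variance configurations, including shifted meals, changed work hours,
a mid-week start, and a work-free schedule.

The stochastic properties are checked on the default configuration: diary
entries always partition the horizon exactly; satiation stays in $[0, 1]$
at every tick (tracked during the run); sampled parameters never leave
$[\mu - \sigma, \mu + \sigma]$ over $10^5$ draws; per-parameter sample
means over 100 simulated weeks (the problem size chosen for the test
suite) recover $\mu$ within three standard errors; and breakfast is absent
on exactly those workdays where the sampled wake time is at or after the
sampled morning commute urge — the skip is verified mechanistically
per-day against the sampled values rather than against any particular
realization.

```{r}
d <- run_simulation(zero_variance(sim_config()), seed = 1)
subset(as.data.frame(d), day == 1)
```

## What the generator does and does not emulate

The synthetic diaries reproduce the coupled structure of a single adult's
weekday routine — linked commutes, an interruptible workday, meals and
sleep that stretch when started late, weekday/weekend contrast, and
correlated morning cascades after oversleeping. They do not emulate:
multi-occupant households or social coordination; children; jobs with
shifts, overtime, or weekend work; meal skipping other than the morning
mechanism; consumer-product use and other within-location behaviors; or
calibration to observed survey data, for which the truncated-normal
parameterization is deliberately survey-shaped (a $\mu$ and $\sigma$ per
activity parameter) but not fitted here. Passing tests therefore
demonstrate internal consistency of the behavioral model, not agreement
with any measured population.

## Known limitations

* The one-sigma truncation makes extreme days impossible by construction;
  real schedules have heavier tails.
* Only the work activity can be interrupted, and only by lunch; urgent
  needs cannot preempt sleep or meals.
* The weekday calendar is fixed (Monday–Friday); there are no holidays.
* A single agent in a fixed three-environment world; no travel other than
  the work commute.
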