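# English abbreviations that end in a period but do not close a sentence.
dr.
drs.
mr.
mrs.
ms.
prof.
rev.
st.
jr.
sr.
vs.
e.g.
i.e.
etc.
approx.
dept.
est.
fig.
hosp.
inc.
min.
max.
no.
oz.
lb.
lbs.
mg.
ml.
vol.
wk.
yr.
a.m.
p.m.
u.s.
jan.
feb.
mar.
apr.
jun.
jul.
aug.
sep.
sept.
oct.
nov.
dec.
mon.
tue.
wed.
thu.
fri.
sat.
sun.
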