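# Default question-cue vocabulary for bigram-pattern induction.
# wh-words, auxiliaries, pronouns, and request cue words; one per line.
who
what
when
where
why
how
which
whom
whose
do
does
did
can
could
should
would
will
shall
may
might
must
is
are
was
were
am
be
been
have
has
had
i
me
my
we
us
our
you
your
it
this
that
these
those
one
anyone
anybody
someone
somebody
else
other
others
similar
wondering
wonder
wanting
want
need
trouble
advice
recommend
recommendations
suggest
suggestions
question
questions
know
help
tell
concerned
worried
experience
idea
ideas
there
out
if
about
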