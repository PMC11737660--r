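# Default stoplist for the built-in word tokenizer (function words whose
# removal mirrors dropping empty morphemes). Fully user-replaceable.
a
an
the
and
or
but
if
then
so
of
to
in
on
at
by
for
with
from
as
is
are
was
were
be
been
being
am
do
does
did
have
has
had
i
me
my
we
our
you
your
he
him
his
she
her
it
its
they
them
their
this
that
these
those
not
no
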