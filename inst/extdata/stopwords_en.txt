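a
an
and
are
as
at
be
been
but
by
for
from
had
has
have
in
into
is
it
its
of
on
or
that
the
their
these
this
those
to
was
we
were
which
with
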